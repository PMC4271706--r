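Package: biomepool
Title: Historical Biogeography and the Assembly of Regional Species Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers how a regional species pool or biome assembles from a
    dated phylogeny: time-stratified dispersal-extinction-cladogenesis
    (DEC, DEC+J, DIVALIKE, BAYAREALIKE) ancestral range estimation with
    founder-event speciation and weighted-AIC model comparison; extraction
    of dated range-expansion and range-restriction events for a focal
    region; dispersal-rate inflection analysis (EDE/ESE estimators);
    Brownian-motion ancestral climate reconstruction with
    threshold-crossing evolutionary-lag classification; phylogenetic
    generalized least squares climate-profile contrasts; and birth-death
    diversification with incomplete sampling, rate-shift scanning, and
    phylogenetic-diversity partitioning of dispersal-derived versus
    in-situ diversity. Includes a full synthetic-data generator (birth-death
    trees, Gillespie range histories with ground truth, Brownian traits,
    noisy occurrence records) so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
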