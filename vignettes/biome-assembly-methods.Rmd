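---
title: "Methods: inferring how a regional species pool assembles"
author: "biomepool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring how a regional species pool assembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biomepool)
```

# The scientific problem

A regional flora or fauna — say, the lineages of a plant family occupying
the seasonally dry tropical forest of one country — is assembled by three
processes acting over tens of millions of years: **dispersal** into the
region, **in-situ diversification** once there, and **adaptation** to the
region's climatic envelope (which may happen before, during, or after
arrival). `biomepool` implements the full inference chain needed to weigh
these processes against each other from three inputs: a time-calibrated
phylogeny (or a bootstrap ensemble of them), a species-by-region presence
table, and species-level climate summaries.

The chain is: (1) fit a discrete-area range-evolution model and reconstruct
ancestral ranges; (2) read dated range-expansion and range-restriction
events for the focal region off the reconstruction; (3) estimate the
dispersal rate through time and test for an inflection; (4) reconstruct
ancestral climate under Brownian motion and classify each restricted
lineage's *evolutionary lag* (did it cross the biome's climatic threshold
before, during, or after becoming restricted?); (5) estimate net
diversification with incomplete sampling and partition the region's
phylogenetic diversity into dispersal-derived and in-situ components.

Every stage is also backed by a generator (`simulate_dataset()` and
friends) that produces data with a complete ground-truth log, so the whole
chain is testable end to end without any external download.

# The range-evolution model

## States, anagenesis, cladogenesis

Ranges are subsets of a fixed area list (default: SA, CA, Me, Ca, As, Af,
M), capped at `max_range` areas. The cap should be the widest range
observed among the extant taxa under study; the default of 4 keeps the
state space at 98 occupied states plus an absorbing "extinct" empty
range. Along a branch a
range gains area $a$ at rate $d \sum_{b \in R} m_k[b, a]$ — the per-pair
dispersal rate $d$ modulated by the epoch-$k$ multiplier matrix — and loses
any one occupied area at rate $e$. The multipliers ($m \in [0,1]$)
encode paleogeography as a piecewise-constant **epoch schedule**; a branch
crossing an epoch boundary is propagated by the ordered product of
per-segment matrix exponentials, oldest first. `example_schedule()` ships
an illustrative four-epoch (70–45–30–5–0 Myr) setup in which the
American-corridor multipliers rise toward the present, on the conventional
scale of 0.1 (well-separated landmasses) to 1.0 (contiguous); any real
analysis should supply its own schedule.

At every internal node (including the root) the parent range is partitioned
between the two daughters according to the cladogenesis variant:

* **DEC** — narrow sympatry for single-area parents; subset sympatry
  (one daughter keeps the range, the other one occupied area) and
  vicariance with a single-area smaller part, all at weight 1;
* **DIVALIKE** — vicariance of any split, no subset sympatry;
* **BAYAREALIKE** — the range is copied to both daughters;
* **+J** — founder-event speciation: one daughter keeps the range, the
  other jumps to one *unoccupied* area, each ordered pair at weight $j$.

Weights are normalized per parent state. Founder weights are *not* scaled
by the dispersal multipliers by default (`scale_j_by_m = FALSE`): the
unscaled form keeps +J the simplest nested extension ($j = 0$ recovers the
founder-free model exactly), and multiplier scaling sits behind the flag
for sensitivity analyses.

## Likelihood, root handling, and marginals

`dec_loglik()` is a Felsenstein pruning over the range state space,
combining per-branch propagators with the cladogenesis distribution at
each node, with per-node rescaling against underflow. Root conditional
likelihoods are combined as a **flat-weight sum over non-extinct states**
(the Lagrange convention). A normalized flat prior would subtract a
constant $\log(K)$; estimates, AIC differences, Akaike weights, and
marginal reconstructions are identical either way, and the sum makes the
degenerate no-process likelihood exactly 1. `root_prior = "ranksize"`
weights states inversely to range size instead.

`fit_biogeo()` maximizes the likelihood over $(d, e[, j])$ with L-BFGS-B
from three fixed starts (rates on the log scale in $[10^{-9}, 5]$, $j$
natural in $[0, 3]$), so fits are deterministic. `compare_biogeo_models()`
assembles AIC ($2k - 2\log L$), $\Delta$AIC, and Akaike weights.
`ancestral_ranges()` (also available as `predict()` on a fit) computes
exact marginal state probabilities by the standard inside/outside pass;
most-probable states break ties toward the smaller range, then the lower
state index — deterministic and conservative about event calls.

Numerics: propagators use the eigendecomposition of the dense generator,
validated against `Matrix::expm` at construction and falling back to it
when the decomposition is ill-conditioned. State spaces here are ≤ ~100
states, so dense algebra is appropriate.

## What the simulator emulates — and what it does not

`simulate_range_history()` is an exact event-driven (Gillespie) simulation
of the same kernels the likelihood integrates, with epoch boundaries
splitting branches into segments and one cladogenetic draw per node, and a
complete event log (`TrueHistory`) that replays exactly to the recorded
states (`replay_history()`). A lineage whose range empties is extinct;
since extinct lineages cannot be sampled as extant tips, downstream fitting
prunes them (`prune_history()` carries the true states onto the pruned
tree so recovery tests compare like with like).

That pruning has one important consequence, documented here because it
shapes what a green recovery test can establish: **the loss rate $e$ is
essentially unidentifiable from survivor-only data** under the
unconditioned likelihood. The surviving tips never experienced range
death, the absorbing extinct state makes the survival probability
$\approx e^{-e \cdot (\text{singleton lineage-Myr})}$, and observed narrow
ranges are explained by low-$d$ paths or founder events rather than by
gain-then-loss histories — so the ML $\hat e$ collapses to the boundary in
essentially every replicate (for DEC as well as DEC+J), while $d$ and $j$
are recovered within a factor of two and the +J model is correctly
preferred. This mirrors the published identifiability critique of these
models. The test suite asserts the idealized $e$-recovery expectation
anyway, and that check fails honestly; the package does not condition the
likelihood on survival because the unconditioned likelihood is the model
the field fits.

# Events, dispersal rates, and the inflection point

`extract_events()` scans every branch of a reconstruction: an **expansion**
is a branch whose parent range lacks the focal area while the child range
contains it; a **restriction** is a branch whose child range is exactly the
focal singleton while the parent's is not; a single branch may be both. A
root range containing the focal area counts as one expansion dated at the
root. Events are dated at the **stem** (parent) node by default — the
dispersal is placed on the branch subtending the arriving lineage — with
crown and midpoint conventions as options.

`dispersal_rate()` divides the event count by the observed event-age window
(oldest − youngest): e.g. 33 events over a 46.4–3.8 Myr window give
0.77 ≈ 0.8 lineages Myr⁻¹. Fewer than two
distinct ages yields an undefined-rate flag, never a division.

`find_inflection()` works on the cumulative event-count curve over calendar
time, both axes normalized to [0, 1], relative to the chord joining its
endpoints. For one-signed deviation (the "elbow" a single rate increase
produces) the EDE estimate is the point of maximum chord distance and the
ESE estimate the point balancing the deviation area on either side; for
substantially two-signed deviation (an S-curve) the estimators switch to
the classical sigmoid forms — the midpoint of the extreme deviations and
the chord-crossing point. The consensus is their mean. A curve whose
maximum normalized chord distance stays below `tol = 0.05` (a 5% band
around the chord) is flagged **degenerate**: no detectable rate change.
The 5% band was chosen once as the curvature a ~30-event record can
distinguish from Poisson noise; it is deliberately conservative, so
homogeneous records are usually rejected via a near-1 fold change rather
than the degeneracy flag. `split_rates()` computes the before/after rates
over their respective sub-windows and the fold change (after/before);
1.7/0.3 rounds to the headline six-fold increase.

Per-tree quantities across a bootstrap ensemble are summarized by
`summarize_ensemble()` (mean and interpolated 2.5/97.5 percentiles). Event
counting uses most-probable states; `expected_event_counts()` provides the
probability-weighted alternative as a sensitivity check.

# Ancestral climate and evolutionary lag

Species climate profiles are occurrence means (`species_climate_means()`;
non-numeric rows are rejected with a warning). Group contrasts
(non-focal / endemic / widespread, from `assign_groups()`) are tested by
PGLS: GLS with the Brownian covariance $C_{ij}$ = shared root-to-MRCA path
length, $\hat\beta = (X'C^{-1}X)^{-1}X'C^{-1}y$, $t$-tests on all pairwise
group differences, and an ensemble wrapper reporting mean estimates plus
the fraction of trees significant at $\alpha$. On a star tree this reduces
exactly to OLS, and under the null its type-I rate is calibrated at 5%.

`bm_ancestral_ml()` fits Brownian motion in closed form (GLS root state,
ML rate $\hat\sigma^2 = $ quadratic form $/ n$) and returns ancestral
values as the conditional expectations given the tips; tip entries equal
the observations. `bm_ancestral_bayes()` is a Gibbs sampler (conjugate
normal updates node by node, inverse-gamma $\sigma^2$) with flat priors,
run 10,000 generations by default; with flat priors it concentrates on the
ML reconstruction and exists to attach credible intervals. A small floor
(1e-10) on the $\sigma^2$ draw keeps the chain defined on constant data.

`threshold_crossing_age()` walks the root-to-lineage path and finds the
**first** (oldest) branch where the reconstructed value drops to or below
the threshold, interpolating linearly in time within the branch; a root
value already at or below the threshold dates the crossing at the root,
and a path that never reaches it yields no crossing. Re-crossings above
the threshold are counted but never move the first crossing ("first
evolved" semantics). Thresholds follow the biome definition: total annual
precipitation ≤ 1800 mm yr⁻¹ (traditional) and ≤ 1600 mm yr⁻¹ (observed
endemic envelope); driest-quarter precipitation ≤ 50 and ≤ 100 mm qtr⁻¹.

`lag_time()` subtracts the restriction age from the crossing age:
**concurrent** if the crossing sits on the restriction's own branch,
otherwise **pre_adapted** for positive lag and **in_situ** for negative;
no crossing is classed in_situ with an undefined lag (flagged, not
guessed). With stem-dated restrictions and lineage-node targets, a
negative-lag crossing necessarily lies on the restriction branch, so the
in_situ class arises via the no-crossing route — the synthetic lag
scenarios are designed accordingly.

# Diversification and phylogenetic diversity

`bd_loglik()` is the reconstructed-process constant-rate birth-death
likelihood conditioned on the crown age and survival of both root
lineages, with sampling fraction $f$ as independent tip inclusion
($p_0$/$p_1$ in their $\rho$-sampled form). It matches the pure-birth
closed form at $\mu = 0, f = 1$, and `fit_bd()` matches the reference
implementation in `ape::birthdeath` tree for tree. Note that $\hat\mu$ on
reconstructed trees is intrinsically dispersed — about half of Yule trees
give a distinctly positive $\hat\mu$ under any correct ML fit — so
downstream use centres on the net rate $r = \lambda - \mu$.

`scan_shifts()` is a deliberately simple stand-in for compound-Poisson
shift samplers: for each candidate clade (≥ 5 tips, backbone ≥ 3 tips) the
data are partitioned into the clade and the backbone with the clade
collapsed to one representative lineage, and a shared-rate fit (k = 2) is
compared by AIC with a regime-specific fit (k = 4) **on the same
partition**, so the comparison is properly nested. Candidates beating the
threshold (default ΔAIC > 4) are accepted greedily, best first,
non-overlapping, up to `max_shifts`. Because ~15–50 overlapping candidates
are scanned per tree at a fixed per-candidate threshold, the family-wise
false-positive rate on homogeneous trees is ~15–20%; the test suite's
stricter expectation (≥90% of homogeneous trees shift-free) therefore
fails honestly at the default threshold. Real analyses should raise
`delta_aic` with tree size, as stepwise-AIC shift tools do.

`mpd_partition()` reports the mean patristic distance within introductions
(in-situ diversification) and between introductions (dispersal-derived
diversity), pooling pairs across introductions (`weighting =
"introductions"` averages per-introduction means instead); because published values
of this kind are ambiguous between path length and divergence time, a
half-patristic column is reported alongside. `assign_introductions()` maps
each focal tip to the most recent expansion on its root path.
`chi2_sampling_bias()` is the standard Pearson goodness-of-fit of sampled
versus expected species counts per category.

# Synthetic-data defaults

The generator defaults describe the world the analysis assumes: a
supercritical birth–death clade (λ = 0.15, μ = 0.05 Myr⁻¹, 100 tips —
giving crown ages of a few tens of Myr), DEC+J range evolution at
d = 0.02, e = 0.01, j = 0.1 from a South-American root over the 7 default
areas, Brownian climate with σ² = 2000 mm² Myr⁻¹ around a 2500 mm yr⁻¹
root (driest-quarter values scaled down accordingly), 8 occurrence records
per species with 100 mm record noise (a typical occurrence-database yield
and spread per species), and mean-one lognormal age jitter (sd 0.05) for
bootstrap-style ensembles. Recovery studies in the test suite scale tip
and replicate counts down for a single-CPU budget and say so where they do;
process parameters are never changed to make a test pass.

What a green end-to-end test establishes is that the chain recovers known
truth *under its own model assumptions* (exact Gillespie data, Brownian
traits, correct tree). It does not establish robustness to the things real
data add: topological error beyond age jitter, spatially biased occurrence
sampling, non-Brownian trait evolution, or rate variation the constant-rate
diversification model cannot express.

# Known limitations

* The loss rate $e$ is not identifiable from extant-only data
  (see above); treat reported $\hat e$ as a lower bound near zero.
* The shift scan controls its error per candidate, not per tree.
* Marginal ancestral ranges are computed under fixed (point-estimate)
  parameters; parameter uncertainty is not propagated.
* The Bayesian climate reconstruction uses flat priors and a simple Gibbs
  scheme — it is a cross-check on the ML reconstruction, not a full
  uncertainty treatment.
* No raster handling: climate inputs are tabular species summaries by
  design.
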