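# End-to-end orchestration: simulate (or load) data, fit the biogeographic
# model, reconstruct ancestral ranges per ensemble tree, extract events and
# rates, detect the dispersal-rate inflection, reconstruct ancestral
# climate and classify evolutionary lags, fit diversification, and
# partition phylogenetic diversity. Deterministic given the master seed.

#' Pipeline configuration
#'
#' Exactly one of `input` (paths to a tree/ensemble file, range table,
#' occurrence table, genus totals) or `sim` (a [simulation_config()]) must
#' be supplied.
#'
#' @param input Optional named list with paths: `trees` (multi-tree Newick),
#'   `ranges` (TSV, 0/1 per area), `occurrences` (CSV), `genus_totals`
#'   (TSV), all tab/comma separated with headers.
#' @param sim Optional [simulation_config()].
#' @param focal Focal area name (default `"Me"`).
#' @param schedule An [epoch_schedule()] or `NULL` for a uniform epoch.
#' @param thresholds List of [threshold_spec()]s for the lag analysis.
#' @param age_convention Event dating convention (see [extract_events()]).
#' @param models Biogeographic models to compare.
#' @param n_ensemble Number of jittered ensemble trees in simulation mode.
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, sim = NULL, focal = "Me",
                            schedule = NULL,
                            thresholds = list(threshold_spec("bio12", 1800),
                                              threshold_spec("bio12", 1600),
                                              threshold_spec("bio17", 50),
                                              threshold_spec("bio17", 100)),
                            age_convention = "stem",
                            models = c("DEC", "DEC+J"), n_ensemble = 10,
                            seed = 1L, out_dir = NULL) {
  if (is.null(input) == is.null(sim))
    stop("supply exactly one of `input` or `sim`")
  if (!is.null(input)) {
    for (p in unlist(input))
      if (!file.exists(p)) stop("input file does not exist: ", p)
  }
  structure(list(input = input, sim = sim, focal = focal,
                 schedule = schedule, thresholds = thresholds,
                 age_convention = age_convention, models = models,
                 n_ensemble = n_ensemble, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate input concordance across data sources
#'
#' Checks tip-label agreement between the tree(s), the range table, and the
#' occurrence table, reporting species present in one input but missing
#' from another. An empty intersection is fatal; partial overlap is
#' reported so that the pipeline can prune accordingly (species without
#' range data are dropped from the biogeographic fit, with logging).
#'
#' @param tree A `phylo` tree (or first ensemble member).
#' @param range_table 0/1 species-by-area table.
#' @param occurrences Occurrence data frame with a `species` column
#'   (optional).
#' @return A list: `tree_only`, `ranges_only`, `no_occurrences`, `shared`.
#' @export
validate_inputs <- function(tree, range_table, occurrences = NULL) {
  tips <- tree$tip.label
  rng <- rownames(range_table)
  shared <- intersect(tips, rng)
  if (length(shared) == 0L)
    stop("fatal: no species shared between tree and range table")
  out <- list(tree_only = setdiff(tips, rng),
              ranges_only = setdiff(rng, tips),
              no_occurrences = character(0),
              shared = shared)
  if (!is.null(occurrences))
    out$no_occurrences <- setdiff(shared, unique(occurrences$species))
  out
}

#' Run the full analysis pipeline
#'
#' Sequences every stage on either simulated or loaded data and returns a
#' machine-readable report. All randomness flows from `config$seed` via
#' fixed per-stage offsets, so repeated runs are identical.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage outputs: `data` provenance,
#'   `model_comparison`, `fit`, per-tree `events`, ensemble summaries of
#'   expansion/restriction counts and rates, `inflection`, `lags` (one
#'   table per threshold) and classification counts, `diversification`,
#'   `mpd`, `timings`, and the echoed `config`.
#' @export
run_pipeline <- function(config) {
  t0 <- proc.time()[3]
  timings <- c()
  tick <- function(name) {
    now <- proc.time()[3]
    timings[name] <<- now - t0
    t0 <<- now
  }
  # --- stage: data ---------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- config$sim
    ds <- simulate_dataset(sim)
    tree <- ds$tree; range_table <- ds$range_table
    occurrences <- ds$occurrences; genus_totals <- ds$genus_totals
    truth <- ds$history
    schedule <- if (is.null(config$schedule)) ds$schedule else config$schedule
    trees <- make_tree_ensemble(tree, config$n_ensemble, 0.05,
                                seed = config$seed + 11L)
  } else {
    trees <- read_tree_ensemble(config$input$trees)
    tree <- trees[[1]]
    range_table <- as.matrix(utils::read.table(config$input$ranges,
                                               header = TRUE, sep = "\t",
                                               row.names = 1))
    occurrences <- if (!is.null(config$input$occurrences))
      utils::read.csv(config$input$occurrences) else NULL
    genus_totals <- if (!is.null(config$input$genus_totals))
      utils::read.table(config$input$genus_totals, header = TRUE, sep = "\t")
    else NULL
    truth <- NULL
    schedule <- config$schedule
  }
  val <- validate_inputs(tree, range_table, occurrences)
  if (length(val$tree_only)) {
    message("pruning ", length(val$tree_only),
            " species without range data from the biogeographic stages")
    trees <- as_tree_ensemble(lapply(trees, prune_tips, drop = val$tree_only))
    tree <- trees[[1]]
  }
  space <- build_state_space(colnames(range_table),
                             max_range = max(rowSums(range_table)))
  if (is.null(schedule)) schedule <- epoch_schedule(n_areas = space$n_areas)
  tick("data")
  # --- stage: biogeographic model fit -------------------------------------
  comparison <- compare_biogeo_models(tree, range_table, config$models,
                                      schedule, space)
  fits <- attr(comparison, "fits")
  best <- fits[[which.max(comparison$weight)]]
  tick("fit_biogeo")
  # --- stage: ancestral ranges + events per ensemble tree ------------------
  per_tree <- lapply(trees, function(tr) {
    anc <- ancestral_ranges(tr, range_table, best$params, schedule, space)
    ev <- extract_events(tr, anc, config$focal,
                         age_convention = config$age_convention)
    list(anc = anc, events = ev)
  })
  exp_counts <- vapply(per_tree, function(z) sum(z$events$type == "expansion"),
                       numeric(1))
  res_counts <- vapply(per_tree, function(z)
    sum(z$events$type == "restriction"), numeric(1))
  rates <- vapply(per_tree, function(z) {
    r <- dispersal_rate(z$events$event_age[z$events$type == "expansion"])
    if (r$defined) r$rate else NA_real_
  }, numeric(1))
  tick("events")
  # --- stage: inflection ----------------------------------------------------
  infl <- lapply(per_tree, function(z) {
    ag <- z$events$event_age[z$events$type == "expansion"]
    if (length(ag) >= 5) find_inflection(ag) else NULL
  })
  t_stars <- vapply(infl, function(x)
    if (is.null(x) || x$degenerate) NA_real_ else x$t_star, numeric(1))
  folds <- vapply(infl, function(x)
    if (is.null(x) || x$degenerate) NA_real_ else x$fold_change, numeric(1))
  tick("inflection")
  # --- stage: climate + lag -------------------------------------------------
  lags <- NULL; lag_counts <- NULL; profile <- NULL
  if (!is.null(occurrences)) {
    profile <- species_climate_means(occurrences)
    traits <- setdiff(names(profile), c("species", "n_records"))
    lags <- list()
    ev1 <- per_tree[[1]]$events
    for (th in config$thresholds) {
      if (!th$trait %in% traits) next
      vals <- stats::setNames(profile[[th$trait]], profile$species)
      vals <- vals[tree$tip.label]
      fit_bm <- bm_ancestral_ml(tree, vals)
      lags[[paste0(th$trait, "_", th$threshold)]] <-
        lag_table(tree, fit_bm, ev1, th)
    }
    lag_counts <- lapply(lags, function(lt) table(factor(lt$class,
      levels = c("pre_adapted", "concurrent", "in_situ"))))
  }
  tick("lag")
  # --- stage: diversification + PD -----------------------------------------
  div_fit <- fit_bd(tree, f = clade_sampling_fraction(tree$tip.label,
                                                      genus_totals))
  shifts <- scan_shifts(tree, genus_totals)
  focal_tips <- rownames(range_table)[range_table[, config$focal] == 1]
  focal_tips <- intersect(focal_tips, tree$tip.label)
  mpd <- NULL
  if (length(focal_tips) >= 2) {
    intro <- assign_introductions(tree, per_tree[[1]]$events, focal_tips)
    if (length(intro) >= 2) mpd <- mpd_partition(tree, intro)
  }
  post_rates <- vapply(infl, function(x)
    if (is.null(x) || x$degenerate) NA_real_ else x$rate_after, numeric(1))
  div_vs_disp <- if (any(is.finite(post_rates)))
    compare_dispersal_vs_diversification(
      post_rates[is.finite(post_rates)], c(div_fit$r, shifts$shifts$r))
  else NULL
  tick("diversification")
  report <- structure(list(
    config = config,
    validation = val,
    model_comparison = as.data.frame(comparison),
    fit = best,
    expansions = summarize_ensemble(exp_counts),
    restrictions = summarize_ensemble(res_counts),
    dispersal_rate = if (any(is.finite(rates)))
      summarize_ensemble(rates) else NULL,
    inflection_age = if (any(is.finite(t_stars)))
      summarize_ensemble(t_stars) else NULL,
    fold_change = if (any(is.finite(folds)))
      summarize_ensemble(folds) else NULL,
    events_per_tree = lapply(per_tree, `[[`, "events"),
    climate_profile = profile,
    lags = lags, lag_counts = lag_counts,
    diversification = div_fit, shift_scan = shifts,
    dispersal_vs_diversification = div_vs_disp,
    mpd = mpd,
    truth = truth,
    timings = timings,
    version = as.character(utils::packageVersion("biomepool"))),
    class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("Best model: ", x$fit$model, "\n")
  cat("Expansions: "); print(x$expansions)
  cat("Restrictions: "); print(x$restrictions)
  if (!is.null(x$dispersal_rate)) { cat("Dispersal rate: "); print(x$dispersal_rate) }
  if (!is.null(x$inflection_age)) { cat("Inflection age: "); print(x$inflection_age) }
  if (!is.null(x$lag_counts)) {
    cat("Lag classification counts:\n")
    for (nm in names(x$lag_counts)) {
      cat("  ", nm, ": ", paste(names(x$lag_counts[[nm]]),
                                x$lag_counts[[nm]], collapse = ", "), "\n")
    }
  }
  cat(sprintf("Net diversification r = %.4g Myr^-1\n", x$diversification$r))
  if (!is.null(x$mpd)) print(x$mpd)
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `report.json` (summaries), per-tree event TSVs, and the lag tables
#' under `dir`.
#'
#' @param report A `run_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summ <- function(s) if (is.null(s)) NULL else
    list(mean = s$mean, q025 = s$q025, q975 = s$q975, n = s$n)
  js <- list(
    seed = report$config$seed,
    best_model = report$fit$model,
    params = unclass(report$fit$params)[c("d", "e", "j", "variant")],
    model_comparison = report$model_comparison,
    expansions = summ(report$expansions),
    restrictions = summ(report$restrictions),
    dispersal_rate = summ(report$dispersal_rate),
    inflection_age = summ(report$inflection_age),
    fold_change = summ(report$fold_change),
    lag_counts = lapply(report$lag_counts, function(tb)
      as.list(stats::setNames(as.integer(tb), names(tb)))),
    diversification = list(lambda = report$diversification$lambda,
                           mu = report$diversification$mu,
                           r = report$diversification$r),
    n_shifts = nrow(report$shift_scan$shifts),
    mpd = if (is.null(report$mpd)) NULL else
      unclass(report$mpd)[c("mpd_in_situ", "mpd_between")],
    timings = as.list(report$timings),
    version = report$version)
  jsonlite::write_json(js, file.path(dir, "report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  for (i in seq_along(report$events_per_tree))
    write_event_table(report$events_per_tree[[i]],
                      file.path(dir, sprintf("events_tree%03d.tsv", i)))
  if (!is.null(report$lags))
    for (nm in names(report$lags))
      utils::write.table(report$lags[[nm]],
                         file.path(dir, paste0("lag_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
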