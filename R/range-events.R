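# Dated range-expansion/restriction events for a focal region, dispersal
# rates through time, inflection-point detection on the cumulative event
# curve, and ensemble summaries.

#' Extract focal-area expansion and restriction events
#'
#' Scans every branch of the tree against a table of (most-probable) node
#' ranges. An *expansion* is a branch whose parent range lacks the focal
#' area while the child range contains it; a *restriction* is a branch whose
#' child range is exactly the focal area while the parent range is not. A
#' single branch can emit both. If the root range already contains the
#' focal area, one expansion is emitted at the root with stem and crown age
#' both equal to the root age.
#'
#' @param tree A dated `phylo` tree.
#' @param ancestral An `ancestral_range_table` (from [ancestral_ranges()] or
#'   [true_focal_events()]'s internal truth table) covering tips and
#'   internal nodes.
#' @param focal Focal area name or index in the table's state space.
#' @param age_convention Event dating convention: `"stem"` (parent node age;
#'   default), `"crown"` (child node age), or `"midpoint"`.
#' @return Data frame of class `event_table`: columns `type`, `parent`,
#'   `child`, `stem_age`, `crown_age`, `parent_range`, `child_range`,
#'   `event_age`.
#' @export
extract_events <- function(tree, ancestral, focal,
                           age_convention = c("stem", "crown", "midpoint")) {
  age_convention <- match.arg(age_convention)
  space <- attr(ancestral, "space")
  if (is.character(focal)) {
    fi <- match(focal, space$areas)
    if (is.na(fi)) stop("focal area not in the area list: ", focal)
  } else fi <- as.integer(focal)
  if (fi < 1L || fi > space$n_areas) stop("focal area index out of range")
  focal_singleton <- state_index(space, fi)
  st <- ancestral$state[order(ancestral$node)]
  ages <- node_ages(tree)
  has_focal <- vapply(st, function(s) fi %in% space$states[[s]], logical(1))
  rows <- list()
  evage <- function(stem, crown) switch(age_convention,
    stem = stem, crown = crown, midpoint = (stem + crown) / 2)
  n <- ape::Ntip(tree); root <- n + 1L
  if (has_focal[root]) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "expansion", parent = NA_integer_, child = root,
      stem_age = ages[root], crown_age = ages[root],
      parent_range = NA_character_, child_range = space$labels[st[root]],
      event_age = ages[root], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    stem <- ages[p]; crown <- ages[ch]
    if (!has_focal[p] && has_focal[ch]) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "expansion", parent = p, child = ch, stem_age = stem,
        crown_age = crown, parent_range = space$labels[st[p]],
        child_range = space$labels[st[ch]],
        event_age = evage(stem, crown), stringsAsFactors = FALSE)
    }
    if (st[ch] == focal_singleton && st[p] != focal_singleton) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "restriction", parent = p, child = ch, stem_age = stem,
        crown_age = crown, parent_range = space$labels[st[p]],
        child_range = space$labels[st[ch]],
        event_age = evage(stem, crown), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(0), parent = integer(0), child = integer(0),
               stem_age = numeric(0), crown_age = numeric(0),
               parent_range = character(0), child_range = character(0),
               event_age = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(-out$event_age, out$child), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("event_table", "data.frame")
  out
}

#' Probability-weighted focal-area event counts
#'
#' Sensitivity companion to [extract_events()]: instead of calling events on
#' most-probable states, sums over branches the probability that the parent
#' lacks the focal area while the child contains it (expansions), and that
#' the child is exactly the focal singleton while the parent is not
#' (restrictions), treating nodes independently.
#'
#' @param tree A dated `phylo` tree.
#' @param ancestral An [ancestral_ranges()] table with its probability
#'   matrix.
#' @param focal Focal area name or index.
#' @return Named numeric vector `c(expansion, restriction)`.
#' @export
expected_event_counts <- function(tree, ancestral, focal) {
  space <- attr(ancestral, "space")
  prob <- attr(ancestral, "prob")
  if (is.null(prob)) stop("ancestral table lacks a probability matrix")
  if (is.character(focal)) focal <- match(focal, space$areas)
  has <- vapply(space$states, function(s) focal %in% s, logical(1))
  fs <- state_index(space, focal)
  p_has <- prob %*% has
  p_restr <- prob[, fs]
  exp_n <- sum((1 - p_has[tree$edge[, 1]]) * p_has[tree$edge[, 2]])
  res_n <- sum((1 - p_restr[tree$edge[, 1]]) * p_restr[tree$edge[, 2]])
  root <- ape::Ntip(tree) + 1L
  exp_n <- exp_n + p_has[root]
  c(expansion = as.numeric(exp_n), restriction = as.numeric(res_n))
}

#' Average dispersal rate over the event window
#'
#' Rate = number of events divided by the width of the observed event-age
#' window (oldest minus youngest event age), in lineages Myr^-1.
#'
#' @param ages Numeric vector of event ages (Myr).
#' @return A `rate_estimate` list: `n_events`, `window`
#'   (`c(oldest, youngest)`), `rate`, `defined`.
#' @export
dispersal_rate <- function(ages) {
  ages <- ages[is.finite(ages)]
  n <- length(ages)
  if (n < 2L || max(ages) == min(ages)) {
    return(structure(list(n_events = n,
                          window = if (n) range(ages) else c(NA, NA),
                          rate = NA_real_, defined = FALSE),
                     class = "rate_estimate"))
  }
  structure(list(n_events = n, window = c(max(ages), min(ages)),
                 rate = n / (max(ages) - min(ages)), defined = TRUE),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  if (!x$defined) cat("Dispersal rate: undefined (", x$n_events, "events )\n")
  else cat(sprintf("Dispersal rate: %d events over %.1f-%.1f Myr = %.3f lineages/Myr\n",
                   x$n_events, x$window[1], x$window[2], x$rate))
  invisible(x)
}

# chord deviations of the normalized cumulative curve; x increases toward
# the present (x = -age), both axes scaled to [0, 1]
cumulative_curve <- function(ages) {
  x <- sort(-ages)
  y <- seq_along(x)
  u <- (x - x[1]) / (x[length(x)] - x[1])
  v <- (y - y[1]) / (y[length(y)] - y[1])
  list(x = x, u = u, v = v, d = v - u)   # perpendicular distance = |d|/sqrt(2)
}

#' Inflection point of the cumulative event curve
#'
#' Builds the cumulative event-count curve over calendar time (x = -age) and
#' locates the point where the event rate changes, using two geometric
#' estimators relative to the chord joining the curve's endpoints (both
#' axes normalized to \code{[0, 1]}).
#'
#' For one-signed deviation (an "elbow" curve, the signature of a single
#' rate change): EDE is the x maximizing the perpendicular chord distance,
#' and ESE the x at which the deviation area on the left balances the area
#' on the right. When the deviation changes sign substantially (an S-shaped
#' curve), EDE is the midpoint of the extreme positive and negative
#' deviations and ESE the chord-crossing point between them, which is how
#' the classical estimators treat sigmoids. The consensus is the mean of
#' the two. Curves whose maximum normalized chord distance falls below
#' `tol` are flagged degenerate (near-linear: no detectable rate change).
#'
#' @param ages Numeric vector of event ages (Myr), at least 5.
#' @param tol Degeneracy tolerance on the normalized chord distance
#'   (default 0.05, i.e. the curve stays within a 5% band of the chord).
#' @return An `inflection_result` list: `t_star` (consensus age, Myr),
#'   `t_star_ede`, `t_star_ese`, `method`, `degenerate`, `rate_before`,
#'   `rate_after`, `fold_change` (via [split_rates()] at the consensus).
#' @export
find_inflection <- function(ages, tol = 0.05) {
  ages <- ages[is.finite(ages)]
  if (length(ages) < 5L) stop("need at least 5 events for inflection analysis")
  cc <- cumulative_curve(ages)
  d <- cc$d
  maxdist <- max(abs(d)) / sqrt(2)
  if (maxdist < tol) {
    return(structure(list(t_star = NA_real_, t_star_ede = NA_real_,
                          t_star_ese = NA_real_, method = "consensus",
                          degenerate = TRUE, rate_before = NA_real_,
                          rate_after = NA_real_, fold_change = NA_real_),
                     class = "inflection_result"))
  }
  two_signed <- max(d) > tol & min(d) < -tol
  if (two_signed) {
    i_hi <- which.max(d); i_lo <- which.min(d)
    x_ede <- (cc$x[i_hi] + cc$x[i_lo]) / 2
    lo <- min(i_hi, i_lo); hi <- max(i_hi, i_lo)
    seg <- lo:hi
    cross <- which(diff(sign(d[seg])) != 0)
    x_ese <- if (length(cross)) {
      i <- seg[cross[1]]
      # linear interpolation of the zero crossing
      cc$x[i] + (cc$x[i + 1] - cc$x[i]) * abs(d[i]) / (abs(d[i]) + abs(d[i + 1]))
    } else x_ede
  } else {
    i_ede <- which.max(abs(d))
    x_ede <- cc$x[i_ede]
    ad <- abs(d)
    # trapezoid cumulative area of |deviation|; balance point splits it in half
    seg_area <- diff(cc$u) * (ad[-1] + ad[-length(ad)]) / 2
    A <- c(0, cumsum(seg_area))
    half <- A[length(A)] / 2
    k <- which(A >= half)[1]
    frac <- if (A[k] == A[k - 1]) 0 else (half - A[k - 1]) / (A[k] - A[k - 1])
    x_ese <- cc$x[k - 1] + frac * (cc$x[k] - cc$x[k - 1])
  }
  t_ede <- -x_ede; t_ese <- -x_ese
  t_star <- (t_ede + t_ese) / 2
  sr <- tryCatch(split_rates(ages, t_star), error = function(e) NULL)
  structure(list(t_star = t_star, t_star_ede = t_ede, t_star_ese = t_ese,
                 method = "consensus", degenerate = FALSE,
                 rate_before = if (is.null(sr)) NA_real_ else sr$rate_before,
                 rate_after = if (is.null(sr)) NA_real_ else sr$rate_after,
                 fold_change = if (is.null(sr)) NA_real_ else sr$fold_change),
            class = "inflection_result")
}

#' @export
print.inflection_result <- function(x, ...) {
  if (x$degenerate) {
    cat("Inflection: degenerate (near-linear cumulative curve)\n")
  } else {
    cat(sprintf("Inflection at %.2f Myr (EDE %.2f, ESE %.2f)\n",
                x$t_star, x$t_star_ede, x$t_star_ese))
    cat(sprintf("  rate before %.3f, after %.3f (fold %.2f)\n",
                x$rate_before, x$rate_after, x$fold_change))
  }
  invisible(x)
}

#' Event rates on either side of an inflection age
#'
#' `rate_before = #(age > t_star) / (oldest - t_star)` and
#' `rate_after = #(age <= t_star) / (t_star - youngest)`; the fold change is
#' their ratio (after/before).
#'
#' @param ages Event ages (Myr).
#' @param t_star Split age, strictly inside the event window.
#' @return List with `rate_before`, `rate_after`, `fold_change`,
#'   `n_before`, `n_after`, `defined`.
#' @export
split_rates <- function(ages, t_star) {
  ages <- ages[is.finite(ages)]
  oldest <- max(ages); youngest <- min(ages)
  if (!(t_star < oldest && t_star > youngest))
    stop("t_star must lie strictly inside the event window")
  n_before <- sum(ages > t_star)
  n_after <- sum(ages <= t_star)
  rb <- n_before / (oldest - t_star)
  ra <- n_after / (t_star - youngest)
  defined <- n_before > 0 && n_after > 0
  list(rate_before = rb, rate_after = ra,
       fold_change = if (n_before > 0) ra / rb else NA_real_,
       n_before = n_before, n_after = n_after, defined = defined)
}

#' Summarize a per-tree quantity across an ensemble
#'
#' Arithmetic mean and empirical 2.5%/97.5% percentiles (linear
#' interpolation) of per-tree values, the ensemble analogue of reporting a
#' mean with a 95% quantile range.
#'
#' @param values Numeric vector (one value per tree); NAs dropped.
#' @return An `ensemble_summary` list: `values`, `n`, `mean`, `q025`,
#'   `q975`, `skewed` (flag set when the quantiles fail to bracket the
#'   mean).
#' @export
summarize_ensemble <- function(values) {
  keep <- is.finite(values)
  v <- values[keep]
  if (length(v) == 0L) stop("no finite values to summarize")
  q <- stats::quantile(v, c(0.025, 0.975), names = FALSE, type = 7)
  m <- mean(v)
  structure(list(values = values, n = length(v), mean = m,
                 q025 = q[1], q975 = q[2],
                 skewed = !(q[1] <= m && m <= q[2])),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("mean %.3f (Q95%%: %.3f-%.3f, n = %d)%s\n", x$mean, x$q025,
              x$q975, x$n, if (x$skewed) " [skewed]" else ""))
  invisible(x)
}

#' Write an event table as TSV
#' @param events An `event_table`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_event_table <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
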