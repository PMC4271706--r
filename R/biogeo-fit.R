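# ML fitting of the DEC-family models and weighted-AIC model comparison.

variant_of <- function(model) {
  base <- sub("\\+J$", "", model)
  if (!base %in% c("DEC", "DIVALIKE", "BAYAREALIKE"))
    stop("unknown model: ", model)
  list(variant = base, plus_j = grepl("\\+J$", model))
}

#' Fit a DEC-family biogeographic model by maximum likelihood
#'
#' Box-constrained multi-start optimization of [dec_loglik()] over the
#' dispersal rate `d`, the loss rate `e`, and (for "+J" models) the
#' founder-event weight `j`. Rates are optimized on the log scale within
#' `d, e in [1e-9, 5]`; `j` is optimized on its natural scale in
#' `[0, j_max]`. Three fixed starting points make the fit deterministic.
#'
#' @param tree A binary dated `phylo` tree with at least 3 tips.
#' @param tip_ranges 0/1 species-by-area table or named state-index vector.
#' @param model One of `"DEC"`, `"DEC+J"`, `"DIVALIKE"`, `"DIVALIKE+J"`,
#'   `"BAYAREALIKE"`, `"BAYAREALIKE+J"`.
#' @param schedule An [epoch_schedule()]; default single uniform epoch.
#' @param space A [build_state_space()] result; inferred from `tip_ranges`
#'   when `NULL`.
#' @param j_max Upper bound for the founder-event weight.
#' @param root_prior Root state prior, `"flat"` or `"ranksize"`.
#' @param starts Optional matrix of starting values (columns `d`, `e`, `j`).
#' @return An object of class `biogeo_fit` with components `params`
#'   ([biogeo_params()]), `logLik`, `k` (parameter count), `AIC`, `model`,
#'   `converged`, and the data needed by [predict.biogeo_fit()] and
#'   [simulate.biogeo_fit()].
#' @seealso [compare_biogeo_models()], [ancestral_ranges()]
#' @export
fit_biogeo <- function(tree, tip_ranges, model = "DEC+J", schedule = NULL,
                       space = NULL, j_max = 3, root_prior = "flat",
                       starts = NULL) {
  if (ape::Ntip(tree) < 3L) stop("need at least 3 tips to fit")
  mv <- variant_of(model)
  if (is.null(space)) space <- infer_space(tip_ranges)
  if (is.null(schedule)) schedule <- epoch_schedule(n_areas = space$n_areas)
  st <- tip_state_vector(space, tree, tip_ranges)
  lb <- log(1e-9); ub <- log(5)
  nll <- function(par) {
    d <- exp(par[1]); e <- exp(par[2])
    j <- if (mv$plus_j) par[3] else 0
    p <- biogeo_params(d, e, j, variant = mv$variant, j_max = j_max)
    ll <- dec_prune(tree, st, p, schedule, space, root_prior)$logL
    if (!is.finite(ll)) 1e10 else -ll
  }
  if (is.null(starts))
    starts <- rbind(c(0.01, 0.01, 0.05), c(0.1, 0.02, 0.5),
                    c(0.02, 0.2, 0.01))
  best <- NULL; any_conv <- FALSE
  for (r in seq_len(nrow(starts))) {
    p0 <- c(log(starts[r, 1]), log(starts[r, 2]))
    lower <- c(lb, lb); upper <- c(ub, ub)
    if (mv$plus_j) {
      p0 <- c(p0, starts[r, 3]); lower <- c(lower, 0); upper <- c(upper, j_max)
    }
    opt <- tryCatch(
      stats::optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 200, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (opt$convergence == 0) any_conv <- TRUE
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("all optimizer starts failed")
  d <- exp(best$par[1]); e <- exp(best$par[2])
  j <- if (mv$plus_j) best$par[3] else 0
  k <- if (mv$plus_j) 3L else 2L
  logL <- -best$value
  fit <- structure(list(
    params = biogeo_params(d, e, j, variant = mv$variant, j_max = j_max),
    logLik = logL, k = k, AIC = 2 * k - 2 * logL, model = model,
    converged = any_conv, tree = tree, tip_ranges = tip_ranges,
    space = space, schedule = schedule, root_prior = root_prior),
    class = "biogeo_fit")
  fit
}

#' @export
print.biogeo_fit <- function(x, ...) {
  cat("Biogeographic model fit:", x$model, "\n")
  cat(sprintf("  d = %.5g  e = %.5g", x$params$d, x$params$e))
  if (grepl("\\+J$", x$model)) cat(sprintf("  j = %.5g", x$params$j))
  cat("\n")
  cat(sprintf("  logLik = %.4f  k = %d  AIC = %.4f\n", x$logLik, x$k, x$AIC))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.biogeo_fit <- function(object, ...) {
  out <- c(d = object$params$d, e = object$params$e)
  if (grepl("\\+J$", object$model)) out <- c(out, j = object$params$j)
  out
}

#' @export
logLik.biogeo_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = ape::Ntip(object$tree),
            class = "logLik")
}

#' @export
summary.biogeo_fit <- function(object, ...) {
  cat("Model:", object$model, "on", ape::Ntip(object$tree), "tips,",
      object$space$n_areas, "areas (max range", object$space$max_range, ")\n")
  print(object)
  invisible(object)
}

#' Predict method: marginal ancestral ranges under the fitted parameters
#' @param object A `biogeo_fit`.
#' @param newtree Optional tree to predict on (defaults to the fitted tree).
#' @param ... Unused.
#' @return An [ancestral_ranges()] table.
#' @export
predict.biogeo_fit <- function(object, newtree = NULL, ...) {
  tree <- if (is.null(newtree)) object$tree else newtree
  ancestral_ranges(tree, object$tip_ranges, object$params, object$schedule,
                   object$space, object$root_prior)
}

#' Simulate method: range histories under the fitted parameters
#' @param object A `biogeo_fit`.
#' @param nsim Number of simulated histories.
#' @param seed Integer seed.
#' @param root_range Root range as area indices or names (default: the
#'   most-probable root state of the fit).
#' @param ... Unused.
#' @return List of [simulate_range_history()] results.
#' @export
simulate.biogeo_fit <- function(object, nsim = 1, seed = NULL,
                                root_range = NULL, ...) {
  if (is.null(root_range)) {
    anc <- predict(object)
    root <- ape::Ntip(object$tree) + 1L
    root_range <- object$space$states[[anc$state[anc$node == root]]]
  }
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(1e6, nsim)
  lapply(seeds, function(s)
    simulate_range_history(object$tree, object$params, object$schedule,
                           root_range, seed = s, space = object$space))
}

#' Compare DEC-family models by weighted AIC
#'
#' Fits each requested model and assembles the comparison table:
#' `AIC = 2k - 2 logL`, differences to the best model, and Akaike weights
#' `w_i = exp(-dAIC_i / 2) / sum_m exp(-dAIC_m / 2)` (summing to 1).
#'
#' @inheritParams fit_biogeo
#' @param models Character vector of model names to compare.
#' @return A `biogeo_model_comparison`: data frame with columns `model`,
#'   `logLik`, `k`, `AIC`, `dAIC`, `weight`; fitted objects in
#'   `attr(, "fits")`.
#' @export
compare_biogeo_models <- function(tree, tip_ranges,
                                  models = c("DEC", "DEC+J"),
                                  schedule = NULL, space = NULL, j_max = 3,
                                  root_prior = "flat") {
  fits <- lapply(models, function(m)
    fit_biogeo(tree, tip_ranges, m, schedule, space, j_max, root_prior))
  names(fits) <- models
  aic <- vapply(fits, `[[`, numeric(1), "AIC")
  ll <- vapply(fits, `[[`, numeric(1), "logLik")
  k <- vapply(fits, `[[`, numeric(1), "k")
  daic <- aic - min(aic)
  w <- exp(-daic / 2); w <- w / sum(w)
  out <- data.frame(model = models, logLik = ll, k = k, AIC = aic,
                    dAIC = daic, weight = w, row.names = NULL)
  attr(out, "fits") <- fits
  class(out) <- c("biogeo_model_comparison", "data.frame")
  out
}

#' @export
print.biogeo_model_comparison <- function(x, ...) {
  cat("Weighted-AIC model comparison\n")
  print.data.frame(x, digits = 5)
  invisible(x)
}
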