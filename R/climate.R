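# Species climate profiles, PGLS group contrasts, Brownian-motion ancestral
# climate reconstruction (ML and Bayesian), threshold-crossing ages, and
# evolutionary-lag classification.

#' Species-level climate means from occurrence records
#'
#' Arithmetic mean per species per trait. Rows with non-numeric or missing
#' trait values are rejected with a warning; species whose rows are all
#' rejected are excluded.
#'
#' @param occurrences Data frame with a `species` column and one numeric
#'   column per trait.
#' @return Data frame of class `climate_profile`: `species`, one mean per
#'   trait, and `n_records`.
#' @export
species_climate_means <- function(occurrences) {
  if (!"species" %in% names(occurrences)) stop("need a `species` column")
  traits <- setdiff(names(occurrences), "species")
  if (length(traits) == 0L) stop("no trait columns")
  df <- occurrences
  for (tr in traits) df[[tr]] <- suppressWarnings(as.numeric(df[[tr]]))
  bad <- !stats::complete.cases(df[traits])
  if (any(bad)) {
    warning(sum(bad), " occurrence rows rejected (non-numeric trait values)")
    df <- df[!bad, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no usable occurrence rows")
  agg <- stats::aggregate(df[traits], by = list(species = df$species), mean)
  cnt <- stats::aggregate(list(n_records = df$species),
                          by = list(species = df$species), length)
  out <- merge(agg, cnt, by = "species")
  class(out) <- c("climate_profile", "data.frame")
  out
}

#' Assign biogeographic group labels relative to a focal area
#'
#' `endemic` species occupy exactly the focal area; `widespread` species
#' include the focal area among several; `non_focal` species do not occur
#' there.
#'
#' @param range_table 0/1 species-by-area matrix or data frame.
#' @param focal Focal area column name.
#' @return Named factor with levels `non_focal`, `endemic`, `widespread`.
#' @export
assign_groups <- function(range_table, focal) {
  tab <- as.matrix(range_table)
  if (!focal %in% colnames(tab)) stop("focal area not in the range table")
  rs <- rowSums(tab)
  if (any(rs == 0))
    stop("species with all-zero range: ",
         paste(rownames(tab)[rs == 0], collapse = ", "))
  lab <- ifelse(tab[, focal] == 0, "non_focal",
                ifelse(rs == 1, "endemic", "widespread"))
  factor(stats::setNames(lab, rownames(tab)),
         levels = c("non_focal", "endemic", "widespread"))
}

#' PGLS group contrast of a climate trait
#'
#' Generalized least squares under the Brownian covariance
#' `C[i, j] = shared root-to-MRCA path length`, with a group factor design
#' (`non_focal` as reference):
#' `beta = (X' C^-1 X)^-1 X' C^-1 y`. Coefficients are reported with
#' t-statistics against `sigma^2 (X' C^-1 X)^-1`, and all pairwise group
#' contrasts with their own standard errors.
#'
#' @param tree A dated `phylo` tree.
#' @param profile A [species_climate_means()] table (or any data frame with
#'   `species` and the trait column).
#' @param labels Named group factor from [assign_groups()].
#' @param trait Trait column to analyse.
#' @return A `pgls_fit` list: `coefficients` (data frame with estimate, SE,
#'   t, p), `contrasts` (pairwise group differences), `sigma2`, `df`, `n`.
#' @export
pgls_group_test <- function(tree, profile, labels, trait) {
  if (!trait %in% names(profile)) stop("trait not in profile: ", trait)
  sp <- intersect(tree$tip.label, profile$species)
  sp <- intersect(sp, names(labels))
  grp <- droplevels(labels[sp])
  if (any(table(grp) < 3) || nlevels(grp) < 2)
    stop("need at least 3 species in each of at least 2 groups; got: ",
         paste(names(table(grp)), table(grp), collapse = ", "))
  tr <- prune_tips(tree, setdiff(tree$tip.label, sp))
  sp <- tr$tip.label
  y <- profile[[trait]][match(sp, profile$species)]
  grp <- droplevels(labels[sp])
  C <- ape::vcv.phylo(tr)[sp, sp]
  X <- stats::model.matrix(~grp)
  Ci <- solve(C)
  XtCi <- crossprod(X, Ci)
  A <- XtCi %*% X
  beta <- solve(A, XtCi %*% y)
  resid <- y - X %*% beta
  n <- length(y); p <- ncol(X)
  sigma2 <- as.numeric(crossprod(resid, Ci %*% resid)) / (n - p)
  Vb <- sigma2 * solve(A)
  se <- sqrt(diag(Vb))
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  coefs <- data.frame(term = colnames(X), estimate = as.numeric(beta),
                      se = se, t = as.numeric(tval), p = as.numeric(pval),
                      row.names = NULL)
  # pairwise group contrasts (differences of group means)
  levs <- levels(droplevels(grp))
  mean_vec <- function(g) {
    v <- numeric(p); v[1] <- 1
    kk <- match(paste0("grp", g), colnames(X))
    if (!is.na(kk)) v[kk] <- 1
    v
  }
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  contr <- do.call(rbind, lapply(pairs, function(pr) {
    cvec <- mean_vec(pr[2]) - mean_vec(pr[1])
    est <- sum(cvec * beta)
    s <- sqrt(as.numeric(t(cvec) %*% Vb %*% cvec))
    tv <- est / s
    data.frame(contrast = paste(pr[2], "-", pr[1]), estimate = est, se = s,
               t = tv, p = 2 * stats::pt(-abs(tv), df = n - p),
               row.names = NULL)
  }))
  structure(list(coefficients = coefs, contrasts = contr, sigma2 = sigma2,
                 df = n - p, n = n, trait = trait),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("PGLS group test on", x$trait, "(n =", x$n, ")\n")
  print(x$coefficients, digits = 4)
  cat("Contrasts:\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

#' PGLS contrasts across a tree ensemble
#'
#' Runs [pgls_group_test()] on every ensemble tree and summarizes each
#' contrast by its mean estimate and the fraction of trees with p < alpha.
#'
#' @param trees A `tree_ensemble` or list of trees.
#' @param profile,labels,trait As in [pgls_group_test()].
#' @param alpha Significance level for the per-tree verdicts.
#' @return Data frame: one row per contrast with `mean_estimate` and
#'   `frac_significant`.
#' @export
pgls_ensemble <- function(trees, profile, labels, trait, alpha = 0.05) {
  fits <- lapply(trees, pgls_group_test, profile = profile, labels = labels,
                 trait = trait)
  cons <- lapply(fits, `[[`, "contrasts")
  nm <- cons[[1]]$contrast
  est <- sapply(cons, function(cc) cc$estimate)
  pv <- sapply(cons, function(cc) cc$p)
  if (is.null(dim(est))) { est <- matrix(est, nrow = 1); pv <- matrix(pv, nrow = 1) }
  data.frame(contrast = nm, mean_estimate = rowMeans(est),
             frac_significant = rowMeans(pv < alpha), row.names = NULL)
}

# covariance of node depths: shared root-to-MRCA path length for every pair
# of nodes (tips and internals), from dist.nodes
node_cov_matrix <- function(tree) {
  D <- ape::dist.nodes(tree)
  depth <- ape::node.depth.edgelength(tree)
  outer(depth, depth, "+") / 2 - D / 2
}

#' Maximum-likelihood Brownian ancestral reconstruction
#'
#' Fits the Brownian-motion model to tip values and returns the ancestral
#' estimates at every internal node as the GLS conditional expectations
#' `E[z_node | tips]` under the fitted root state and rate:
#' `mu = (1' C^-1 y) / (1' C^-1 1)`, `sigma2 = (y - mu)' C^-1 (y - mu) / n`
#' (the ML rate), and node estimates `mu + c_node' C^-1 (y - mu)` where
#' `c_node` holds the node-tip shared path lengths. Tip "estimates" equal
#' the observations.
#'
#' @param tree A dated `phylo` tree (>= 2 tips).
#' @param tip_values Named numeric vector covering every tip.
#' @return A `bm_fit` list: `sigma2`, `root_state`, `ace` (estimates for all
#'   nodes, tips first), `logLik`, `n`.
#' @export
bm_ancestral_ml <- function(tree, tip_values) {
  n <- ape::Ntip(tree)
  if (n < 2L) stop("need at least 2 tips")
  miss <- setdiff(tree$tip.label, names(tip_values))
  if (length(miss)) stop("tips without values: ", paste(miss, collapse = ", "))
  y <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(y)) stop("missing tip values")
  Cfull <- node_cov_matrix(tree)
  tipidx <- seq_len(n)
  C <- Cfull[tipidx, tipidx]
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- as.numeric(crossprod(one, Ci %*% y) / crossprod(one, Ci %*% one))
  dev <- y - mu
  q <- as.numeric(crossprod(dev, Ci %*% dev))
  sigma2 <- q / n
  logLik <- if (sigma2 > 0)
    -0.5 * (n * log(2 * pi * sigma2) + determinant(C)$modulus + n)
  else Inf
  allidx <- seq_len(n + tree$Nnode)
  est <- numeric(n + tree$Nnode)
  est[tipidx] <- y
  inner <- Ci %*% dev
  for (v in setdiff(allidx, tipidx)) {
    cn <- Cfull[v, tipidx]
    est[v] <- mu + as.numeric(cn %*% inner)
  }
  names(est) <- c(tree$tip.label, paste0("N", n + seq_len(tree$Nnode)))
  structure(list(sigma2 = sigma2, root_state = mu, ace = est,
                 logLik = as.numeric(logLik), n = n, tree = tree),
            class = "bm_fit")
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("Brownian-motion fit: sigma2 = %.5g, root = %.5g, logLik = %.3f (n = %d)\n",
              x$sigma2, x$root_state, x$logLik, x$n))
  invisible(x)
}

#' Bayesian Brownian ancestral reconstruction (MCMC)
#'
#' Gibbs sampler over internal node states and the Brownian rate with flat
#' priors: each internal value is conjugately normal given its neighbors,
#' and `sigma2` is sampled from its inverse-gamma full conditional. With
#' flat priors the posterior concentrates on the ML reconstruction; this
#' implementation exists to mirror the common ML + Bayesian pairing and to
#' attach credible intervals.
#'
#' @param tree A dated `phylo` tree.
#' @param tip_values Named numeric vector covering every tip.
#' @param n_iter MCMC generations (default 10000).
#' @param burnin Fraction discarded (default 0.2).
#' @param seed Integer seed.
#' @return A `bm_bayes` list: `mean`, `ci` (2.5/97.5% per node),
#'   `sigma2_mean`, `acceptance` (1 for Gibbs updates), `n_iter`.
#' @export
bm_ancestral_bayes <- function(tree, tip_values, n_iter = 10000,
                               burnin = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree); Nn <- tree$Nnode
  y <- as.numeric(tip_values[tree$tip.label])
  if (anyNA(y)) stop("missing tip values")
  ml <- bm_ancestral_ml(tree, tip_values)
  vals <- ml$ace
  sigma2 <- max(ml$sigma2, 1e-8)
  edge <- tree$edge; elen <- tree$edge.length
  nb <- lapply(seq_len(n + Nn), function(v) {
    up <- which(edge[, 2] == v)
    down <- which(edge[, 1] == v)
    cbind(node = c(edge[up, 1], edge[down, 2]), len = c(elen[up], elen[down]))
  })
  internals <- n + seq_len(Nn)
  keep <- floor(n_iter * burnin):n_iter
  draws <- matrix(NA_real_, length(keep), Nn)
  s2draws <- numeric(length(keep))
  ptr <- 1L
  for (it in seq_len(n_iter)) {
    for (v in internals) {
      nbv <- nb[[v]]
      w <- 1 / (sigma2 * pmax(nbv[, "len"], 1e-12))
      m <- sum(vals[nbv[, "node"]] * w) / sum(w)
      vals[v] <- stats::rnorm(1, m, sqrt(1 / sum(w)))
    }
    ss <- sum((vals[edge[, 2]] - vals[edge[, 1]])^2 / pmax(elen, 1e-12))
    m_edges <- nrow(edge)
    # floor keeps the chain alive on (near-)constant data, where the
    # posterior for sigma2 collapses toward zero
    sigma2 <- max(ss / (2 * stats::rgamma(1, shape = m_edges / 2 - 1,
                                          rate = 1)), 1e-10)
    if (it >= keep[1]) {
      draws[ptr, ] <- vals[internals]
      s2draws[ptr] <- sigma2
      ptr <- ptr + 1L
    }
  }
  ci <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.975)))
  est <- colMeans(draws)
  names(est) <- paste0("N", internals)
  rownames(ci) <- names(est)
  structure(list(mean = est, ci = ci, sigma2_mean = mean(s2draws),
                 sigma2_draws = s2draws, acceptance = 1, n_iter = n_iter),
            class = "bm_bayes")
}

#' Climatic threshold specification
#'
#' A lineage "reaches" the biome condition when its reconstructed trait
#' value drops to or below the threshold (e.g. total annual precipitation
#' <= 1800 mm yr^-1, or driest-quarter precipitation <= 50 mm qtr^-1).
#'
#' @param trait Trait name.
#' @param threshold Positive threshold value.
#' @return A `threshold_spec` list.
#' @export
threshold_spec <- function(trait, threshold) {
  if (threshold <= 0) stop("threshold must be positive")
  structure(list(trait = trait, threshold = threshold),
            class = "threshold_spec")
}

#' First threshold-crossing age along a root-to-node path
#'
#' Walks from the root toward the target node over reconstructed values and
#' finds the first (oldest) branch on which the value passes from above to
#' at-or-below the threshold; the crossing age is linearly interpolated in
#' time within that branch. If the root value is already at or below the
#' threshold the crossing age is the root age; if the path never reaches
#' the threshold the record is empty. Later re-crossings above the
#' threshold are counted but do not move the (first) crossing.
#'
#' @param tree A dated `phylo` tree.
#' @param fit A [bm_ancestral_ml()] fit (or any object with an `ace` vector
#'   over all nodes) on this tree.
#' @param target Target node number (tip or internal).
#' @param spec A [threshold_spec()].
#' @return A `crossing_record` list: `target`, `crossing_age` (NA if
#'   never), `branch` (child node of the crossing branch, NA at root),
#'   `recrossings`.
#' @export
threshold_crossing_age <- function(tree, fit, target, spec) {
  n <- ape::Ntip(tree)
  if (target < 1 || target > n + tree$Nnode) stop("target not in tree")
  vals <- fit$ace
  ages <- node_ages(tree)
  path <- root_path(tree, target)
  th <- spec$threshold
  v <- vals[path]; a <- ages[path]
  recross <- 0L
  if (v[1] <= th) {
    below <- v <= th
    recross <- sum(diff(below) < 0)
    return(structure(list(target = target, crossing_age = a[1],
                          branch = NA_integer_, recrossings = recross,
                          spec = spec), class = "crossing_record"))
  }
  crossing_age <- NA_real_; branch <- NA_integer_
  for (i in seq_len(length(path) - 1L)) {
    vp <- v[i]; vc <- v[i + 1L]
    if (is.na(crossing_age) && vp > th && vc <= th) {
      crossing_age <- a[i] - (a[i] - a[i + 1L]) * (vp - th) / (vp - vc)
      branch <- path[i + 1L]
    } else if (!is.na(crossing_age) && vp <= th && vc > th) {
      recross <- recross + 1L
    }
  }
  structure(list(target = target, crossing_age = crossing_age,
                 branch = branch, recrossings = recross, spec = spec),
            class = "crossing_record")
}

#' Evolutionary lag between threshold crossing and geographic restriction
#'
#' Lag = crossing age minus restriction age (positive when the climatic
#' threshold was reached before the lineage became restricted to the focal
#' region). Classification: `concurrent` when the crossing lies on the same
#' branch as the restriction event; otherwise `pre_adapted` for positive
#' lag and `in_situ` for negative lag. A lineage that never reaches the
#' threshold is classed `in_situ` with an undefined lag.
#'
#' @param restriction One row of an [extract_events()] table (type
#'   `restriction`).
#' @param crossing A [threshold_crossing_age()] record for the same lineage
#'   (its `target` must equal the restriction's child node).
#' @return A `lag_record` list: `child`, `threshold`, `crossing_age`,
#'   `restriction_age`, `lag`, `class`.
#' @export
lag_time <- function(restriction, crossing) {
  if (!identical(as.integer(restriction$child), as.integer(crossing$target)))
    stop("restriction and crossing refer to different lineages")
  ra <- restriction$event_age
  ca <- crossing$crossing_age
  if (is.na(ca)) {
    cls <- "in_situ"; lag <- NA_real_
  } else if (!is.na(crossing$branch) &&
             crossing$branch == restriction$child &&
             ca <= restriction$stem_age && ca >= restriction$crown_age) {
    cls <- "concurrent"; lag <- ca - ra
  } else {
    lag <- ca - ra
    cls <- if (lag > 0) "pre_adapted" else "in_situ"
  }
  structure(list(child = restriction$child,
                 threshold = crossing$spec$threshold,
                 trait = crossing$spec$trait,
                 crossing_age = ca, restriction_age = ra, lag = lag,
                 class = cls), class = "lag_record")
}

#' Lag table for all restrictions under one threshold
#'
#' Convenience wrapper: runs [threshold_crossing_age()] for the child node
#' of every restriction event and classifies each with [lag_time()].
#'
#' @param tree A dated `phylo` tree.
#' @param fit A [bm_ancestral_ml()] fit on this tree.
#' @param events An [extract_events()] table.
#' @param spec A [threshold_spec()].
#' @return Data frame: one row per restriction with crossing age, lag, and
#'   class.
#' @export
lag_table <- function(tree, fit, events, spec) {
  res <- events[events$type == "restriction", , drop = FALSE]
  if (nrow(res) == 0L)
    return(data.frame(child = integer(0), threshold = numeric(0),
                      crossing_age = numeric(0), restriction_age = numeric(0),
                      lag = numeric(0), class = character(0)))
  rows <- lapply(seq_len(nrow(res)), function(i) {
    cr <- threshold_crossing_age(tree, fit, res$child[i], spec)
    lr <- lag_time(res[i, ], cr)
    data.frame(child = lr$child, threshold = lr$threshold,
               crossing_age = ifelse(is.na(lr$crossing_age), NA, lr$crossing_age),
               restriction_age = lr$restriction_age,
               lag = ifelse(is.na(lr$lag), NA, lr$lag), class = lr$class,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
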