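# Dispersal-extinction-cladogenesis machinery: discrete-area range state
# space, instantaneous rate matrices, epoch-stratified branch propagators,
# cladogenesis distributions (DEC / DIVALIKE / BAYAREALIKE, each with an
# optional founder-event component), and the pruning likelihood.

#' Default area set
#'
#' Seven biogeographic regions used as the default coding: South America
#' (SA), Central America (CA), Mexico (Me), Caribbean (Ca), Asia (As),
#' Africa (Af), Madagascar (M).
#' @export
default_areas <- function() c("SA", "CA", "Me", "Ca", "As", "Af", "M")

#' Build a range state space
#'
#' Enumerates every non-empty subset of the area set up to `max_range`
#' areas, plus the reserved empty ("extinct") state at index 1. Ordering is
#' deterministic: the extinct state first, then by range size, then by
#' bitmask value (areas ordered as given). Capping the range size at the
#' maximum observed among extant taxa keeps the state space tractable and
#' mirrors standard practice.
#'
#' @param areas Character vector of area names, or a single integer count.
#' @param max_range Maximum number of areas a lineage may occupy.
#' @return An object of class `range_state_space`: list with `areas`,
#'   `max_range`, `states` (list of integer area-index vectors; the first is
#'   the empty extinct state), `bits` (bitmask per state), `n_states`, and
#'   `labels` (e.g. `"SA+Me"`, `"(extinct)"`).
#' @examples
#' sp <- build_state_space(c("A", "B", "C"), max_range = 2)
#' sp$labels
#' @export
build_state_space <- function(areas = default_areas(), max_range = 4L) {
  if (is.numeric(areas) && length(areas) == 1L)
    areas <- paste0("A", seq_len(areas))
  n <- length(areas)
  if (anyDuplicated(areas)) stop("duplicate area names")
  if (max_range < 1L || max_range > n)
    stop("max_range must be between 1 and the number of areas")
  states <- list(integer(0))
  for (s in seq_len(max_range))
    states <- c(states, combn(n, s, simplify = FALSE))
  bits <- vapply(states, function(st) sum(2^(st - 1L)), numeric(1))
  # order: extinct, then size, then bitmask
  sizes <- lengths(states)
  ord <- order(sizes, bits)
  states <- states[ord]; bits <- bits[ord]
  labels <- vapply(states, function(st)
    if (length(st) == 0L) "(extinct)" else paste(areas[st], collapse = "+"),
    character(1))
  lookup <- integer(2^n)
  lookup[bits + 1L] <- seq_along(states)
  structure(list(areas = areas, n_areas = n, max_range = as.integer(max_range),
                 states = states, bits = bits, labels = labels,
                 n_states = length(states), lookup = lookup),
            class = "range_state_space")
}

#' @export
print.range_state_space <- function(x, ...) {
  cat("Range state space:", x$n_areas, "areas (",
      paste(x$areas, collapse = ", "), "), max range", x$max_range, "\n")
  cat(x$n_states - 1L, "occupied states + 1 extinct state\n")
  invisible(x)
}

# index of the state holding exactly `areas_idx` (integer area indices)
state_index <- function(space, areas_idx) {
  b <- sum(2^(sort(unique(areas_idx)) - 1L))
  i <- space$lookup[b + 1L]
  if (i == 0L && b != 0L)
    stop("range {", paste(space$areas[areas_idx], collapse = ","),
         "} is not in the state space (max_range = ", space$max_range, ")")
  if (b == 0L) 1L else i
}

#' Convert a species-by-area 0/1 table to state indices
#'
#' @param space A `range_state_space`.
#' @param range_table Matrix or data frame with species as rows and one 0/1
#'   column per area (column names must match `space$areas`).
#' @return Named integer vector of state indices.
#' @export
ranges_to_states <- function(space, range_table) {
  range_table <- as.matrix(range_table)
  if (!all(space$areas %in% colnames(range_table)))
    stop("range table must have one column per area: ",
         paste(space$areas, collapse = ", "))
  range_table <- range_table[, space$areas, drop = FALSE]
  if (!all(range_table %in% c(0, 1))) stop("range table must be 0/1")
  out <- integer(nrow(range_table))
  for (i in seq_len(nrow(range_table))) {
    idx <- which(range_table[i, ] == 1)
    if (length(idx) == 0L)
      stop("species ", rownames(range_table)[i], " has an empty range")
    out[i] <- state_index(space, idx)
  }
  names(out) <- rownames(range_table)
  out
}

#' Biogeographic process parameters
#'
#' @param d Per-area-pair dispersal (range-expansion) rate, Myr^-1.
#' @param e Per-area loss (range-contraction) rate, Myr^-1.
#' @param j Founder-event weight at cladogenesis (dimensionless);
#'   `j = 0` recovers the founder-free model.
#' @param variant Cladogenesis variant: `"DEC"`, `"DIVALIKE"` or
#'   `"BAYAREALIKE"`.
#' @param j_max Upper bound for `j` (used by the fitter).
#' @return A `biogeo_params` list.
#' @export
biogeo_params <- function(d, e, j = 0, variant = c("DEC", "DIVALIKE",
                                                   "BAYAREALIKE"),
                          j_max = 3) {
  variant <- match.arg(variant)
  if (d < 0 || e < 0) stop("d and e must be non-negative")
  if (j < 0 || j > j_max) stop("j must lie in [0, ", j_max, "]")
  structure(list(d = d, e = e, j = j, variant = variant, j_max = j_max),
            class = "biogeo_params")
}

#' Epoch schedule of dispersal multipliers
#'
#' Piecewise-constant dispersal-multiplier matrices over geological time.
#' `boundaries` are ages in Myr before present, strictly decreasing and
#' ending at 0; epoch `k` spans `(boundaries[k+1], boundaries[k]]`, and any
#' age older than `boundaries[1]` uses the first epoch. The default is a
#' single epoch with all multipliers 1 (no stratification). A classic
#' four-epoch setup uses boundaries `c(70, 45, 30, 5, 0)` with entries
#' between 0.1 (well-separated areas) and 1 (contiguous landmasses).
#'
#' @param boundaries Numeric vector of epoch edges, decreasing, last 0.
#' @param multipliers A single n-areas x n-areas matrix (recycled across
#'   epochs) or a list with one matrix per epoch; entries in `[0, 1]`,
#'   diagonal ignored.
#' @param n_areas Number of areas (used to build default all-ones
#'   multipliers).
#' @return An `epoch_schedule` object.
#' @export
epoch_schedule <- function(boundaries = c(Inf, 0), multipliers = NULL,
                           n_areas = 7L) {
  if (any(diff(boundaries) >= 0)) stop("boundaries must be strictly decreasing")
  if (tail(boundaries, 1) != 0) stop("boundaries must end at 0")
  K <- length(boundaries) - 1L
  if (is.null(multipliers))
    multipliers <- matrix(1, n_areas, n_areas)
  if (is.matrix(multipliers)) multipliers <- rep(list(multipliers), K)
  if (length(multipliers) != K)
    stop("need one multiplier matrix per epoch (", K, ")")
  for (m in multipliers) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop("multiplier matrices must be square")
    off <- m[row(m) != col(m)]
    if (any(off < 0 | off > 1)) stop("multiplier entries must lie in [0, 1]")
  }
  structure(list(boundaries = boundaries, multipliers = multipliers,
                 n_epochs = K), class = "epoch_schedule")
}

#' Example stratified schedule for the 7-area world
#'
#' An illustrative four-epoch schedule (70-45, 45-30, 30-5, 5-0 Myr) for the
#' default seven areas in which dispersal multipliers rise from 0.1 between
#' well-separated landmasses toward 1 between contiguous ones as the
#' American land connections develop; Old World/New World multipliers stay
#' low throughout. Values are illustrative defaults, not estimates.
#'
#' @return An `epoch_schedule` for [default_areas()].
#' @export
example_schedule <- function() {
  areas <- default_areas()
  n <- length(areas)
  base <- matrix(0.1, n, n, dimnames = list(areas, areas))
  diag(base) <- 1
  near <- function(m, a, b, v) { m[a, b] <- v; m[b, a] <- v; m }
  m1 <- base
  m1 <- near(m1, "SA", "Af", 0.3)   # early Cenozoic: closer Atlantic
  m1 <- near(m1, "Af", "M", 0.5)
  m1 <- near(m1, "SA", "CA", 0.2); m1 <- near(m1, "CA", "Me", 0.5)
  m1 <- near(m1, "Me", "Ca", 0.3); m1 <- near(m1, "CA", "Ca", 0.3)
  m2 <- near(m1, "SA", "Af", 0.1)   # Atlantic widens
  m2 <- near(m2, "As", "Me", 0.2)   # Beringia/North Atlantic routes
  m3 <- near(m2, "SA", "CA", 0.5)   # proto-Central American corridor
  m3 <- near(m3, "CA", "Me", 1.0); m3 <- near(m3, "SA", "Ca", 0.3)
  m4 <- near(m3, "SA", "CA", 1.0)   # isthmus closure
  m4 <- near(m4, "CA", "Me", 1.0); m4 <- near(m4, "Me", "Ca", 0.5)
  epoch_schedule(c(70, 45, 30, 5, 0), list(m1, m2, m3, m4), n_areas = n)
}

# epoch index for an age (ages above the oldest boundary -> epoch 1)
epoch_of_age <- function(schedule, age) {
  b <- schedule$boundaries
  k <- findInterval(-age, -b, rightmost.closed = FALSE)
  max(1L, min(k, schedule$n_epochs))
}

#' Instantaneous rate matrix for one epoch
#'
#' Anagenetic generator over the range state space: a range `R` expands into
#' area `a` (if the enlarged range respects `max_range`) at rate
#' `d * sum_{b in R} m[b, a]`, and loses any one occupied area at rate `e`;
#' losing the last area enters the absorbing extinct state. Rows sum to
#' zero.
#'
#' @param space A `range_state_space`.
#' @param d,e Dispersal and loss rates (Myr^-1).
#' @param m Dispersal multiplier matrix for the epoch.
#' @return Dense `n_states` x `n_states` matrix.
#' @export
build_rate_matrix <- function(space, d, e, m) {
  if (!is.matrix(m) || nrow(m) != space$n_areas || ncol(m) != space$n_areas)
    stop("multiplier matrix dimension mismatch: need ", space$n_areas,
         " x ", space$n_areas)
  S <- space$n_states
  Q <- matrix(0, S, S)
  for (i in seq_len(S)[-1]) {
    R <- space$states[[i]]
    s <- length(R)
    if (s + 1L <= space$max_range && d > 0) {
      for (a in setdiff(seq_len(space$n_areas), R)) {
        rate <- d * sum(m[R, a])
        if (rate > 0) Q[i, state_index(space, c(R, a))] <-
            Q[i, state_index(space, c(R, a))] + rate
      }
    }
    if (e > 0) {
      for (a in R) {
        tgt <- if (s == 1L) 1L else state_index(space, setdiff(R, a))
        Q[i, tgt] <- Q[i, tgt] + e
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# propagator factory: returns function(t) = expm(Q t), via eigendecomposition
# when numerically safe, falling back to Matrix::expm otherwise
make_propagator <- function(Q) {
  S <- nrow(Q)
  eg <- tryCatch(eigen(Q), error = function(e) NULL)
  use_eigen <- FALSE
  if (!is.null(eg)) {
    Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
    if (!is.null(Vi)) {
      tchk <- 1
      Pe <- Re(eg$vectors %*% (exp(eg$values * tchk) * Vi))
      Pr <- as.matrix(Matrix::expm(Q * tchk))
      if (max(abs(Pe - Pr)) < 1e-9) use_eigen <- TRUE
    }
  }
  if (use_eigen) {
    V <- eg$vectors; val <- eg$values
    function(t) {
      if (t == 0) return(diag(S))
      P <- Re(V %*% (exp(val * t) * Vi))
      P[P < 0] <- 0
      P
    }
  } else {
    function(t) {
      if (t == 0) return(diag(S))
      P <- as.matrix(Matrix::expm(Q * t))
      P[P < 0] <- 0
      P
    }
  }
}

# per-epoch generators + propagators for a parameter set
build_epoch_propagators <- function(space, params, schedule) {
  Qs <- lapply(schedule$multipliers, function(m)
    build_rate_matrix(space, params$d, params$e, m))
  list(Qs = Qs, props = lapply(Qs, make_propagator))
}

# split the age interval [t_end, t_start] at epoch boundaries; rows are
# (start_age, end_age, epoch), oldest first
segment_branch <- function(schedule, t_start, t_end) {
  if (t_start < t_end) stop("negative branch duration")
  cuts <- schedule$boundaries
  inner <- cuts[cuts < t_start & cuts > t_end]
  pts <- c(t_start, inner, t_end)
  k <- vapply(seq_len(length(pts) - 1L), function(i)
    epoch_of_age(schedule, (pts[i] + pts[i + 1L]) / 2), integer(1))
  cbind(start = pts[-length(pts)], end = pts[-1], epoch = k)
}

#' Branch transition probabilities under a stratified schedule
#'
#' Transition probability matrix for a branch running from age `t_start`
#' (older) to `t_end` (younger): the ordered product of per-epoch-segment
#' matrix exponentials, oldest segment applied first. Rows are stochastic;
#' tiny negative entries from the exponential are clipped to zero.
#'
#' @param space A `range_state_space`.
#' @param params A `biogeo_params`.
#' @param schedule An `epoch_schedule`.
#' @param t_start,t_end Branch start/end ages in Myr (`t_start >= t_end`).
#' @return `n_states` x `n_states` matrix; entry `[i, j]` is the probability
#'   of state `j` at the branch end given state `i` at the start.
#' @export
branch_transition_probs <- function(space, params, schedule, t_start, t_end) {
  ep <- build_epoch_propagators(space, params, schedule)
  branch_P(ep$props, schedule, t_start, t_end)
}

# internal: propagator-list version (props from build_epoch_propagators)
branch_P <- function(props, schedule, t_start, t_end, cache = NULL) {
  if (schedule$n_epochs == 1L) {
    if (t_start < t_end) stop("negative branch duration")
    return(props[[1L]](t_start - t_end))
  }
  seg <- segment_branch(schedule, t_start, t_end)
  P <- NULL
  for (i in seq_len(nrow(seg))) {
    dt <- seg[i, "start"] - seg[i, "end"]
    k <- seg[i, "epoch"]
    Pi <- if (!is.null(cache)) {
      key <- paste0(k, "_", dt)
      got <- cache[[key]]
      if (is.null(got)) { got <- props[[k]](dt); cache[[key]] <- got }
      got
    } else props[[k]](dt)
    P <- if (is.null(P)) Pi else P %*% Pi
  }
  P
}

#' Cladogenesis distribution at a node
#'
#' Probability distribution over ordered daughter-range pairs given the
#' parent range, following the chosen cladogenesis variant. For `DEC`:
#' single-area parents copy themselves (narrow sympatry); wider parents
#' allow subset sympatry (one daughter keeps the full range, the other one
#' occupied area; weight 1 per ordered pair) and vicariance with the smaller
#' part a single area (weight 1). `DIVALIKE` drops subset sympatry and
#' allows any vicariant split; `BAYAREALIKE` allows only the identical-copy
#' outcome. With `j > 0`, founder events add ordered pairs pairing the full
#' parent range with a single *unoccupied* area, each with weight `j`
#' (not scaled by dispersal multipliers unless `scale_j_by_m` and a
#' multiplier matrix are supplied). Weights are normalized per parent state.
#'
#' @param parent Parent range given as integer area indices, an area-name
#'   character vector, or a state index (single integer > 0 interpreted as a
#'   state index when `as_state_index = TRUE`).
#' @param params A `biogeo_params`.
#' @param space A `range_state_space`.
#' @param m Optional multiplier matrix for founder scaling (off by default).
#' @param scale_j_by_m If `TRUE`, founder weights become
#'   `j * mean_{b in R} m[b, a]`.
#' @return Data frame with columns `left`, `right` (state indices),
#'   `left_label`, `right_label`, `prob`.
#' @export
cladogenesis_distribution <- function(parent, params, space, m = NULL,
                                      scale_j_by_m = FALSE) {
  if (is.character(parent)) {
    parent <- match(parent, space$areas)
    if (anyNA(parent)) stop("unknown area name in parent range")
  }
  pidx <- state_index(space, parent)
  if (pidx == 1L) stop("cladogenesis undefined for the extinct state")
  tab <- clado_table(space, params, m = m, scale_j_by_m = scale_j_by_m)
  sel <- tab$parent == pidx
  data.frame(left = tab$left[sel], right = tab$right[sel],
             left_label = space$labels[tab$left[sel]],
             right_label = space$labels[tab$right[sel]],
             prob = tab$prob[sel])
}

# full cladogenesis table over all parent states: list of parallel vectors
# (parent, left, right, prob), probabilities normalized within parent
clado_table <- function(space, params, m = NULL, scale_j_by_m = FALSE) {
  j <- params$j; variant <- params$variant
  n <- space$n_areas
  parent <- left <- right <- integer(0)
  weight <- numeric(0)
  add <- function(p, l, r, w) {
    parent <<- c(parent, p); left <<- c(left, l); right <<- c(right, r)
    weight <<- c(weight, w)
  }
  for (i in seq_len(space$n_states)[-1]) {
    R <- space$states[[i]]
    s <- length(R)
    if (variant == "BAYAREALIKE") {
      add(i, i, i, 1)
    } else if (s == 1L) {
      add(i, i, i, 1)
    } else if (variant == "DEC") {
      for (a in R) {
        ai <- state_index(space, a)
        add(i, i, ai, 1); add(i, ai, i, 1)        # subset sympatry
      }
      seen <- character(0)
      for (a in R) {                               # vicariance, small part = 1
        l <- state_index(space, a); r <- state_index(space, setdiff(R, a))
        for (pr in list(c(l, r), c(r, l))) {
          key <- paste(pr, collapse = "_")
          if (!(key %in% seen)) { seen <- c(seen, key); add(i, pr[1], pr[2], 1) }
        }
      }
    } else { # DIVALIKE: all ordered vicariant splits, no subset sympatry
      for (sz in seq_len(s - 1L)) {
        for (X in combn(R, sz, simplify = FALSE)) {
          add(i, state_index(space, X), state_index(space, setdiff(R, X)), 1)
        }
      }
    }
    if (j > 0) {
      for (a in setdiff(seq_len(n), R)) {
        w <- if (scale_j_by_m && !is.null(m)) j * mean(m[R, a]) else j
        if (w > 0) {
          ai <- state_index(space, a)
          add(i, i, ai, w); add(i, ai, i, w)
        }
      }
    }
  }
  tot <- tapply(weight, parent, sum)
  prob <- weight / as.numeric(tot[as.character(parent)])
  list(parent = parent, left = left, right = right, prob = prob)
}

# observed tip states from ranges argument: accepts named integer state
# vector or a 0/1 table
tip_state_vector <- function(space, tree, tip_ranges) {
  if (is.matrix(tip_ranges) || is.data.frame(tip_ranges)) {
    st <- ranges_to_states(space, tip_ranges)
  } else if (is.numeric(tip_ranges)) {
    st <- as.integer(tip_ranges)
    names(st) <- names(tip_ranges)
  } else stop("tip_ranges must be a 0/1 table or named state-index vector")
  miss <- setdiff(tree$tip.label, names(st))
  if (length(miss) > 0)
    stop("tips missing from range table: ", paste(miss, collapse = ", "))
  st <- st[tree$tip.label]
  if (any(st == 1L)) stop("tips may not be in the extinct state")
  st
}

# core pruning engine; returns logL plus (optionally) the per-node inside
# partials and per-edge propagated vectors needed for marginals
dec_prune <- function(tree, tip_states, params, schedule, space,
                      root_prior = c("flat", "ranksize"), keep = FALSE) {
  root_prior <- match.arg(root_prior)
  if (!ape::is.binary(tree)) stop("DEC likelihood requires a binary tree")
  n <- ape::Ntip(tree); Nn <- tree$Nnode
  S <- space$n_states
  ages <- node_ages(tree)
  ep <- build_epoch_propagators(space, params, schedule)
  cache <- if (schedule$n_epochs > 1L) new.env(parent = emptyenv()) else NULL
  ct <- clado_table(space, params)
  tre <- stats::reorder(tree, "postorder")
  edge <- tre$edge
  inside <- matrix(0, S, n + Nn)    # inside partial at each node (post-clado)
  inside[cbind(tip_states, seq_len(n))] <- 1
  logscale <- numeric(n + Nn)
  W <- vector("list", nrow(edge))   # propagated child partial per edge
  Pm <- if (keep) vector("list", nrow(edge)) else NULL
  child_edges <- vector("list", n + Nn)
  for (i in seq_len(nrow(edge))) {
    par <- edge[i, 1]; ch <- edge[i, 2]
    P <- branch_P(ep$props, schedule, ages[par], ages[ch], cache)
    if (keep) Pm[[i]] <- P
    W[[i]] <- as.numeric(P %*% inside[, ch])
    child_edges[[par]] <- c(child_edges[[par]], i)
    if (length(child_edges[[par]]) == 2L) {
      e1 <- child_edges[[par]][1]; e2 <- child_edges[[par]][2]
      vals <- ct$prob * W[[e1]][ct$left] * W[[e2]][ct$right]
      L <- numeric(S)
      acc <- rowsum(matrix(vals, ncol = 1), ct$parent)
      L[as.integer(rownames(acc))] <- acc
      sc <- sum(L)
      if (sc <= 0 || !is.finite(sc)) {
        return(list(logL = -Inf))
      }
      inside[, par] <- L / sc
      kids <- edge[child_edges[[par]], 2]
      logscale[par] <- log(sc) + sum(logscale[kids])
    } else {
      # pass scale through for when parent combines
      logscale[ch] <- logscale[ch]
    }
  }
  root <- n + 1L
  # root handling: conditional likelihoods combined over non-extinct root
  # states with flat weight 1 (Lagrange-style sum; equivalent to a flat
  # prior up to an additive constant, so estimates, dAIC and marginals are
  # unaffected), or weights inversely proportional to range size
  prior <- numeric(S)
  if (root_prior == "flat") {
    prior[-1] <- 1
  } else {
    prior[-1] <- 1 / lengths(space$states)[-1]
  }
  # accumulate scalers: logscale at root already includes all descendants
  logL <- log(sum(prior * inside[, root])) + logscale[root]
  if (!keep) return(list(logL = logL))
  list(logL = logL, inside = inside, W = W, P = Pm, edge = edge,
       child_edges = child_edges, prior = prior, clado = ct, ages = ages,
       logscale = logscale)
}

#' DEC-family log-likelihood
#'
#' Felsenstein-style pruning over the range state space, combining
#' epoch-stratified branch propagators with the cladogenesis distribution at
#' every internal node (including the root). Root conditional likelihoods
#' are averaged under a flat prior over non-extinct states by default.
#'
#' @param tree A binary dated `phylo` tree.
#' @param tip_ranges 0/1 species-by-area table (rows named by tip label) or
#'   a named vector of state indices.
#' @param params A `biogeo_params`.
#' @param schedule An `epoch_schedule`; defaults to a single uniform epoch.
#' @param space A `range_state_space`; defaults to one built from the
#'   columns of `tip_ranges` with `max_range` the maximum observed range
#'   size.
#' @param root_prior `"flat"` (default) or `"ranksize"` (weights inversely
#'   proportional to range size).
#' @return Log-likelihood (scalar).
#' @export
dec_loglik <- function(tree, tip_ranges, params, schedule = NULL,
                       space = NULL, root_prior = "flat") {
  if (is.null(space)) space <- infer_space(tip_ranges)
  if (is.null(schedule))
    schedule <- epoch_schedule(n_areas = space$n_areas)
  st <- tip_state_vector(space, tree, tip_ranges)
  dec_prune(tree, st, params, schedule, space, root_prior)$logL
}

# build a state space from a 0/1 range table (max_range = max observed)
infer_space <- function(tip_ranges) {
  if (!(is.matrix(tip_ranges) || is.data.frame(tip_ranges)))
    stop("cannot infer a state space from state indices; pass `space`")
  tab <- as.matrix(tip_ranges)
  build_state_space(colnames(tab), max_range = max(rowSums(tab)))
}

#' Marginal ancestral range estimates
#'
#' Marginal probability of every range state at every internal node, via the
#' standard inside/outside (down-pass/up-pass) conditioning under fixed
#' parameters. The most-probable state is recorded with a deterministic
#' tie-break: smaller range first, then lower state index. Tip rows carry
#' their observed state with probability 1.
#'
#' @inheritParams dec_loglik
#' @return An object of class `ancestral_range_table`: data frame with
#'   columns `node`, `is_tip`, `label`, `stem_age`, `crown_age`, `state`
#'   (most-probable state index), `state_label`, plus an attached
#'   probability matrix in `attr(, "prob")` (nodes x states) and the state
#'   space in `attr(, "space")`.
#' @export
ancestral_ranges <- function(tree, tip_ranges, params, schedule = NULL,
                             space = NULL, root_prior = "flat") {
  if (is.null(space)) space <- infer_space(tip_ranges)
  if (is.null(schedule)) schedule <- epoch_schedule(n_areas = space$n_areas)
  st <- tip_state_vector(space, tree, tip_ranges)
  pr <- dec_prune(tree, st, params, schedule, space, root_prior, keep = TRUE)
  if (!is.finite(pr$logL)) stop("likelihood underflow: data impossible under parameters")
  n <- ape::Ntip(tree); Nn <- tree$Nnode; S <- space$n_states
  root <- n + 1L
  edge <- pr$edge
  outside <- matrix(0, S, n + Nn)   # outside partial at each node (pre-clado view)
  outside[, root] <- pr$prior
  ct <- pr$clado
  # preorder = reverse postorder on edges
  for (i in rev(seq_len(nrow(edge)))) {
    par <- edge[i, 1]; ch <- edge[i, 2]
    sib_e <- setdiff(pr$child_edges[[par]], i)
    Wsib <- pr$W[[sib_e]]
    o <- outside[, par]
    # distribute over cladogenesis: this child takes the "left" role and the
    # sibling the "right" role; the table holds both orders explicitly
    contrib <- o[ct$parent] * ct$prob * Wsib[ct$right]
    Otop <- numeric(S)
    acc <- rowsum(matrix(contrib, ncol = 1), ct$left)
    Otop[as.integer(rownames(acc))] <- acc
    ob <- as.numeric(crossprod(pr$P[[i]], Otop))
    s <- sum(ob)
    outside[, ch] <- if (s > 0) ob / s else ob
  }
  prob <- matrix(0, n + Nn, S)
  for (v in seq_len(n + Nn)) {
    m <- outside[, v] * pr$inside[, v]
    if (v == root) m <- pr$prior * pr$inside[, v]
    s <- sum(m)
    prob[v, ] <- if (s > 0) m / s else m
  }
  prob[seq_len(n), ] <- 0
  prob[cbind(seq_len(n), st)] <- 1
  sizes <- lengths(space$states)
  best <- apply(prob, 1, function(p) {
    o <- order(-p, sizes, seq_len(S))
    o[1]
  })
  pv <- parent_vector(tree)
  stem <- ifelse(pv == 0L, pr$ages[root], pr$ages[pmax(pv, 1L)])
  out <- data.frame(
    node = seq_len(n + Nn),
    is_tip = seq_len(n + Nn) <= n,
    label = c(tree$tip.label, paste0("N", seq_len(Nn) + n)),
    stem_age = stem,
    crown_age = pr$ages,
    state = best,
    state_label = space$labels[best],
    stringsAsFactors = FALSE)
  attr(out, "prob") <- prob
  attr(out, "space") <- space
  attr(out, "logL") <- pr$logL
  class(out) <- c("ancestral_range_table", "data.frame")
  out
}

#' Write an ancestral range table as TSV
#' @param x An `ancestral_range_table`.
#' @param path Output file.
#' @param digits Probability rounding for the output (default full).
#' @return The path, invisibly.
#' @export
write_ancestral_table <- function(x, path, digits = 6) {
  prob <- attr(x, "prob")
  space <- attr(x, "space")
  colnames(prob) <- space$labels
  df <- cbind(as.data.frame(x), round(prob, digits))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
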