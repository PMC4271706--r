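# Synthetic-data generators with known ground truth: birth-death trees,
# Gillespie range histories under the DEC(+J) process, Brownian climate
# traits, noisy occurrence records, and jittered tree ensembles. All
# generators are pure functions of (arguments, seed).

#' Simulation configuration
#'
#' Bundles the generator settings for an end-to-end synthetic dataset. The
#' defaults describe a mid-sized clade: 100 extant tips from a supercritical
#' birth-death process, a DEC+J range process over the 7 default areas with
#' moderate dispersal and rare local loss, Brownian climate traits on a
#' precipitation-like scale, and a handful of noisy occurrence records per
#' species.
#'
#' @param n_tips Number of extant tips.
#' @param birth_rate,death_rate Birth-death rates, events Myr^-1
#'   (`birth_rate > death_rate >= 0`).
#' @param d,e,j DEC+J process parameters (see [biogeo_params()]).
#' @param variant Cladogenesis variant.
#' @param schedule An [epoch_schedule()] (default: single uniform epoch).
#' @param root_range Root range, area names or indices.
#' @param bm_sigma2 Brownian trait variance per Myr (trait units^2).
#' @param bm_root Trait value at the root.
#' @param occurrence_k Occurrence records per species.
#' @param occurrence_noise_sd Record-level noise SD (trait units).
#' @param areas Area names for the range process (default [default_areas()]).
#' @param max_range Range-size cap for the state space.
#' @param seed Integer master seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_tips = 100, birth_rate = 0.15,
                              death_rate = 0.05, d = 0.02, e = 0.01,
                              j = 0.1, variant = "DEC",
                              schedule = NULL, root_range = "SA",
                              bm_sigma2 = 2000, bm_root = 2500,
                              occurrence_k = 8, occurrence_noise_sd = 100,
                              areas = default_areas(), max_range = 4L,
                              seed = 1L) {
  stopifnot(birth_rate > 0, death_rate >= 0, birth_rate > death_rate,
            bm_sigma2 > 0, occurrence_k >= 1, n_tips >= 2,
            is.finite(c(birth_rate, death_rate, d, e, j)))
  structure(list(n_tips = n_tips, birth_rate = birth_rate,
                 death_rate = death_rate, d = d, e = e, j = j,
                 variant = variant, schedule = schedule,
                 root_range = root_range, bm_sigma2 = bm_sigma2,
                 bm_root = bm_root, occurrence_k = occurrence_k,
                 occurrence_noise_sd = occurrence_noise_sd,
                 areas = areas, max_range = as.integer(max_range),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a birth-death tree conditioned on its extant tip count
#'
#' Wraps [ape::rphylo()] (reconstructed birth-death process conditioned on
#' `n` survivors); tips are relabeled `t1..tn` and the result validated.
#'
#' @param birth_rate,death_rate Rates in events Myr^-1
#'   (`birth_rate > death_rate >= 0`).
#' @param n_tips Number of extant tips (>= 2).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` tree.
#' @export
simulate_bd_tree <- function(birth_rate, death_rate, n_tips, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  if (!(birth_rate > death_rate && death_rate >= 0))
    stop("need birth_rate > death_rate >= 0")
  if (!is.null(seed)) set.seed(seed)
  # generous stem-age ceiling so conditioning on n tips is not truncated
  T0 <- max(50, 10 * log(n_tips + 1) / (birth_rate - death_rate))
  tr <- ape::rphylo(n_tips, birth_rate, death_rate, T0 = T0)
  tr$tip.label <- paste0("t", seq_len(n_tips))
  validate_dated_tree(tr)
  tr
}

#' Simulate a range history under the DEC(+J) process
#'
#' Exact event-driven (Gillespie) simulation of anagenetic dispersal and
#' local loss along every branch, with epoch boundaries splitting branches
#' into segments governed by their own multiplier matrices, and one
#' cladogenetic outcome drawn at every internal node (including the root)
#' from [cladogenesis_distribution()] applied to the range at the node.
#' A lineage whose range empties is flagged extinct; its whole subtree
#' inherits the extinct state.
#'
#' @param tree A binary dated `phylo` tree.
#' @param params A [biogeo_params()].
#' @param schedule An [epoch_schedule()] (default single uniform epoch).
#' @param root_range Root range as area indices or names.
#' @param seed Integer seed.
#' @param space Optional [build_state_space()]; default 7 areas, max range 4.
#' @return A `range_history` list: `tip_states` (named state indices, 1 =
#'   extinct), `node_states` (state at every node, post-anagenesis),
#'   `daughter_states` (2-column matrix of daughter start states per node),
#'   `events` (data frame: branch child node, type `gain`/`loss`, area,
#'   age), `extinct_tips`, plus the `space`, `params`, `schedule` used.
#' @export
simulate_range_history <- function(tree, params, schedule = NULL,
                                   root_range = "SA", seed = NULL,
                                   space = NULL) {
  if (is.null(space)) space <- build_state_space()
  if (is.null(schedule)) schedule <- epoch_schedule(n_areas = space$n_areas)
  if (is.character(root_range)) {
    root_range <- match(root_range, space$areas)
    if (anyNA(root_range)) stop("unknown area in root_range")
  }
  if (length(root_range) == 0L) stop("root_range must be non-empty")
  if (length(root_range) > space$max_range)
    stop("root_range exceeds max_range")
  if (!is.null(seed)) set.seed(seed)
  if (!ape::is.binary(tree)) stop("need a binary tree")
  n <- ape::Ntip(tree); Nn <- tree$Nnode
  ages <- node_ages(tree)
  root <- n + 1L
  node_state <- integer(n + Nn)      # state at the node (post-anagenesis)
  daughter <- matrix(NA_integer_, n + Nn, 2)
  ev_child <- integer(0); ev_type <- character(0)
  ev_area <- integer(0); ev_age <- numeric(0)
  ct <- clado_table(space, params)
  draw_clado <- function(state_idx) {
    sel <- which(ct$parent == state_idx)
    pick <- sel[sample.int(length(sel), 1, prob = ct$prob[sel])]
    c(ct$left[pick], ct$right[pick])
  }
  node_state[root] <- state_index(space, root_range)
  # walk one branch from parent age to child age; returns end state,
  # recording events against the child node
  walk <- function(state, child, a_from, a_to) {
    seg <- segment_branch(schedule, a_from, a_to)
    for (si in seq_len(nrow(seg))) {
      a <- seg[si, "start"]; a_end <- seg[si, "end"]
      m <- schedule$multipliers[[seg[si, "epoch"]]]
      repeat {
        if (state == 1L) return(1L)
        R <- space$states[[state]]
        s <- length(R)
        gains <- if (s < space$max_range)
          vapply(seq_len(space$n_areas), function(aa)
            if (aa %in% R) 0 else params$d * sum(m[R, aa]), numeric(1))
        else numeric(space$n_areas)
        loss_rate <- params$e * s
        tot <- sum(gains) + loss_rate
        if (tot <= 0) break
        wait <- stats::rexp(1, tot)
        if (a - wait < a_end) break
        a <- a - wait
        if (stats::runif(1) < loss_rate / tot) {
          drop_a <- R[sample.int(s, 1)]
          state <- if (s == 1L) 1L else state_index(space, setdiff(R, drop_a))
          ev_child <<- c(ev_child, child); ev_type <<- c(ev_type, "loss")
          ev_area <<- c(ev_area, drop_a); ev_age <<- c(ev_age, a)
        } else {
          gain_a <- sample.int(space$n_areas, 1, prob = gains)
          state <- state_index(space, c(R, gain_a))
          ev_child <<- c(ev_child, child); ev_type <<- c(ev_type, "gain")
          ev_area <<- c(ev_area, gain_a); ev_age <<- c(ev_age, a)
        }
      }
    }
    state
  }
  # preorder traversal from the root
  edge <- stats::reorder(tree, "postorder")$edge
  kids_of <- function(v) edge[edge[, 1] == v, 2]
  process <- function(v) {
    st <- node_state[v]
    if (st == 1L) {
      if (v > n) for (ch in kids_of(v)) { node_state[ch] <<- 1L; process(ch) }
      return(invisible())
    }
    if (v > n) {
      dk <- draw_clado(st)
      daughter[v, ] <<- dk
      ch <- kids_of(v)
      for (i in 1:2) {
        end <- walk(dk[i], ch[i], ages[v], ages[ch[i]])
        node_state[ch[i]] <<- end
        process(ch[i])
      }
    }
    invisible()
  }
  process(root)
  tip_states <- node_state[seq_len(n)]
  names(tip_states) <- tree$tip.label
  events <- data.frame(child = ev_child, type = ev_type, area = ev_area,
                       age = ev_age, stringsAsFactors = FALSE)
  structure(list(tip_states = tip_states, node_states = node_state,
                 daughter_states = daughter, events = events,
                 extinct_tips = tree$tip.label[tip_states == 1L],
                 tree = tree, space = space, params = params,
                 schedule = schedule),
            class = "range_history")
}

#' Replay a range history from the root
#'
#' Reconstructs every node state by applying the logged cladogenetic
#' outcomes and anagenetic events in age order along each branch, and
#' checks the result against the recorded states. Used as a consistency
#' property of the simulator.
#'
#' @param history A `range_history`.
#' @return `TRUE` invisibly if the replay reproduces all recorded states;
#'   otherwise an error.
#' @export
replay_history <- function(history) {
  tree <- history$tree; space <- history$space
  n <- ape::Ntip(tree)
  pv <- parent_vector(tree)
  edge <- stats::reorder(tree, "postorder")$edge  # same order the simulator used
  for (v in seq_len(n + tree$Nnode)) {
    p <- pv[v]
    if (p == 0L) next
    start <- history$daughter_states[p, which(edge[edge[, 1] == p, 2] == v)]
    if (is.na(start)) { # parent extinct
      if (history$node_states[v] != 1L) stop("replay mismatch at node ", v)
      next
    }
    ev <- history$events[history$events$child == v, , drop = FALSE]
    ev <- ev[order(-ev$age), , drop = FALSE]
    st <- start
    for (i in seq_len(nrow(ev))) {
      R <- space$states[[st]]
      if (ev$type[i] == "gain") {
        st <- state_index(space, c(R, ev$area[i]))
      } else {
        st <- if (length(R) == 1L) 1L else state_index(space, setdiff(R, ev$area[i]))
      }
    }
    if (st != history$node_states[v]) stop("replay mismatch at node ", v)
  }
  invisible(TRUE)
}

#' True focal-area events from a simulated history
#'
#' Extracts the ground-truth expansion/restriction events for a focal area
#' from a `range_history`, using the same node-state conventions as
#' [extract_events()] so recovery tests compare like with like.
#'
#' @param history A `range_history`.
#' @param focal Focal area name or index.
#' @param age_convention `"stem"` (default), `"crown"`, or `"midpoint"`.
#' @return An event data frame in the [extract_events()] format.
#' @export
true_focal_events <- function(history, focal, age_convention = "stem") {
  tab <- history_state_table(history)
  extract_events(history$tree, tab, focal, age_convention = age_convention)
}

#' Restrict a range history to surviving tips
#'
#' Lineages whose range empties are extinct and unobservable; this helper
#' prunes them from the tree and carries the true node states over to the
#' retained nodes (degree-2 nodes created by pruning are suppressed, so
#' every retained node keeps its original true state). The result is the
#' truth table an inference run on the pruned tree should be compared
#' against.
#'
#' @param history A `range_history`.
#' @param drop Tip labels to remove (default: the extinct tips).
#' @return List: `tree` (pruned), `truth` (an `ancestral_range_table` of
#'   true states on the pruned tree).
#' @export
prune_history <- function(history, drop = history$extinct_tips) {
  tree <- history$tree; space <- history$space
  n <- ape::Ntip(tree)
  tagged <- tree
  tagged$node.label <- paste0("N", n + seq_len(tree$Nnode))
  pruned <- prune_tips(tagged, drop)
  np <- ape::Ntip(pruned)
  orig_internal <- as.integer(sub("^N", "", pruned$node.label))
  states <- c(history$tip_states[pruned$tip.label],
              history$node_states[orig_internal])
  ages <- node_ages(pruned)
  pv <- parent_vector(pruned)
  stem <- ifelse(pv == 0L, ages[np + 1L], ages[pmax(pv, 1L)])
  out <- data.frame(
    node = seq_len(np + pruned$Nnode),
    is_tip = seq_len(np + pruned$Nnode) <= np,
    label = c(pruned$tip.label, pruned$node.label),
    stem_age = stem, crown_age = ages,
    state = as.integer(states),
    state_label = space$labels[states],
    stringsAsFactors = FALSE)
  attr(out, "space") <- space
  class(out) <- c("ancestral_range_table", "data.frame")
  list(tree = pruned, truth = out)
}

# build an ancestral_range_table-like object from simulator truth
history_state_table <- function(history) {
  tree <- history$tree; space <- history$space
  n <- ape::Ntip(tree); Nn <- tree$Nnode
  ages <- node_ages(tree)
  pv <- parent_vector(tree)
  stem <- ifelse(pv == 0L, ages[n + 1L], ages[pmax(pv, 1L)])
  out <- data.frame(
    node = seq_len(n + Nn),
    is_tip = seq_len(n + Nn) <= n,
    label = c(tree$tip.label, paste0("N", seq_len(Nn) + n)),
    stem_age = stem, crown_age = ages,
    state = history$node_states,
    state_label = space$labels[history$node_states],
    stringsAsFactors = FALSE)
  attr(out, "space") <- space
  class(out) <- c("ancestral_range_table", "data.frame")
  out
}

#' Simulate Brownian-motion traits on a tree
#'
#' Child value ~ Normal(parent value + shift, sigma2 * branch length), with
#' optional per-clade mean shifts applied on the branch subtending the named
#' node. All node values are returned as ground truth.
#'
#' @param tree A dated `phylo` tree.
#' @param sigma2 Trait variance per Myr (> 0).
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @param shifts Optional data frame with columns `node` (ape node number)
#'   and `delta` (added to the Brownian increment of the branch leading to
#'   that node, hence inherited by the whole clade).
#' @return Numeric vector of values for all nodes (tips first, ape order),
#'   with tip labels as names on the tip entries.
#' @export
simulate_bm_traits <- function(tree, sigma2, root_value, seed = NULL,
                               shifts = NULL) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  vals <- numeric(n + tree$Nnode)
  vals[n + 1L] <- root_value
  edge <- stats::reorder(tree, "postorder")$edge
  elen <- stats::reorder(tree, "postorder")$edge.length
  shift_of <- numeric(n + tree$Nnode)
  if (!is.null(shifts)) shift_of[shifts$node] <- shifts$delta
  for (i in rev(seq_len(nrow(edge)))) {  # preorder
    par <- edge[i, 1]; ch <- edge[i, 2]
    vals[ch] <- vals[par] + shift_of[ch] +
      stats::rnorm(1, 0, sqrt(sigma2 * elen[i]))
  }
  names(vals) <- c(tree$tip.label, rep("", tree$Nnode))
  vals
}

#' Simulate occurrence records around species trait means
#'
#' Generates `k` records per species; each record value is
#' Normal(tip value, noise_sd^2) per trait. This creates the raw table that
#' species-level averaging consumes.
#'
#' @param tip_values Named numeric vector (one trait) or a species x trait
#'   matrix with row names.
#' @param k Records per species (>= 1).
#' @param noise_sd Record-level noise SD (single value or one per trait).
#' @param seed Integer seed.
#' @return Data frame with columns `species` and one column per trait.
#' @export
simulate_occurrences <- function(tip_values, k, noise_sd, seed = NULL) {
  if (k < 1) stop("k must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(tip_values)))
    tip_values <- matrix(tip_values, ncol = 1,
                         dimnames = list(names(tip_values), "trait1"))
  noise_sd <- rep(noise_sd, length.out = ncol(tip_values))
  sp <- rep(rownames(tip_values), each = k)
  out <- data.frame(species = sp, stringsAsFactors = FALSE)
  for (jx in seq_len(ncol(tip_values))) {
    mu <- rep(tip_values[, jx], each = k)
    out[[colnames(tip_values)[jx]]] <-
      mu + stats::rnorm(length(mu), 0, noise_sd[jx])
  }
  out
}

#' Jittered tree ensemble emulating bootstrap age uncertainty
#'
#' Internal node ages are perturbed multiplicatively by mean-one lognormal
#' factors (`exp(rnorm(0, sd) - sd^2/2)`), in preorder so each node resamples
#' until it stays strictly younger than its (already-jittered) parent and
#' older than its direct tip children; tip ages are untouched. Branch
#' lengths are rebuilt from the new ages, so every member passes dated-tree
#' validation.
#'
#' @param tree Source `phylo` tree.
#' @param n_trees Ensemble size (>= 1).
#' @param age_jitter_sd Lognormal SD of the age multiplier (0 = copies).
#' @param seed Integer seed.
#' @return A `tree_ensemble` list of `phylo` trees.
#' @export
make_tree_ensemble <- function(tree, n_trees, age_jitter_sd = 0.05,
                               seed = NULL) {
  if (n_trees < 1) stop("n_trees must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  ages <- node_ages(tree)
  edge <- stats::reorder(tree, "postorder")$edge
  pv <- parent_vector(tree)
  out <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    new_age <- ages
    if (age_jitter_sd > 0) {
      for (i in rev(seq_len(nrow(edge)))) {       # preorder over edges
        ch <- edge[i, 2]
        if (ch <= n) next                         # tips fixed
        upper <- new_age[pv[ch]]
        tipkids <- edge[edge[, 1] == ch & edge[, 2] <= n, 2]
        lower <- if (length(tipkids)) max(ages[tipkids]) else 0
        ok <- FALSE
        for (try in 1:100) {
          f <- exp(stats::rnorm(1, 0, age_jitter_sd) - age_jitter_sd^2 / 2)
          a <- ages[ch] * f
          if (a < upper && a > lower) { ok <- TRUE; break }
        }
        new_age[ch] <- if (ok) a else (upper + max(lower, 0)) / 2
      }
      # root jitter too
      rt <- n + 1L
      kidmax <- max(new_age[edge[edge[, 1] == rt, 2]])
      for (try in 1:100) {
        f <- exp(stats::rnorm(1, 0, age_jitter_sd) - age_jitter_sd^2 / 2)
        a <- ages[rt] * f
        if (a > kidmax) break
      }
      new_age[rt] <- if (a > kidmax) a else kidmax * 1.01
    }
    tr <- tree
    tr$edge.length <- new_age[tr$edge[, 1]] - new_age[tr$edge[, 2]]
    validate_dated_tree(tr)
    out[[t]] <- tr
  }
  as_tree_ensemble(out)
}

#' Generate a full synthetic dataset with ground truth
#'
#' Runs the generator chain of a [simulation_config()]: birth-death tree,
#' DEC(+J) range history (rejecting histories with extinct tips so all
#' downstream stages see occupied ranges), Brownian climate traits for two
#' precipitation-like variables, noisy occurrence records, genus totals for
#' sampling fractions, and the complete truth log.
#'
#' @param config A [simulation_config()].
#' @param max_tries Rejection cap: a history is resimulated when fewer than
#'   half of the tips survive the range process.
#' @return A list: `tree` (pruned to range-surviving tips), `range_table`
#'   (0/1 species x areas for survivors), `occurrences`, `genus_totals`,
#'   `history` (truth on the full tree), `truth` (truth table on the pruned
#'   tree, see [prune_history()]), `full_tree`, `traits` (true node values,
#'   two columns, full tree), `space`, `config`.
#' @export
simulate_dataset <- function(config, max_tries = 20) {
  set.seed(config$seed)
  full_tree <- simulate_bd_tree(config$birth_rate, config$death_rate,
                                config$n_tips, seed = config$seed)
  space <- build_state_space(config$areas, config$max_range)
  schedule <- if (is.null(config$schedule))
    epoch_schedule(n_areas = space$n_areas) else config$schedule
  params <- biogeo_params(config$d, config$e, config$j,
                          variant = config$variant)
  hist <- NULL
  for (i in seq_len(max_tries)) {
    h <- simulate_range_history(full_tree, params, schedule,
                                config$root_range, seed = config$seed + i,
                                space = space)
    if (length(h$extinct_tips) <= config$n_tips / 2) { hist <- h; break }
  }
  if (is.null(hist))
    stop("simulation failure: range process kept killing most tips after ",
         max_tries, " tries")
  pr <- prune_history(hist)
  tree <- pr$tree
  surv <- tree$tip.label
  range_table <- t(vapply(hist$tip_states[surv], function(s) {
    r <- integer(space$n_areas); r[space$states[[s]]] <- 1L; r
  }, integer(space$n_areas)))
  colnames(range_table) <- space$areas
  rownames(range_table) <- surv
  tr1 <- simulate_bm_traits(full_tree, config$bm_sigma2, config$bm_root,
                            seed = config$seed + 101)
  tr2 <- simulate_bm_traits(full_tree, config$bm_sigma2 / 16,
                            config$bm_root / 12, seed = config$seed + 102)
  n <- ape::Ntip(full_tree)
  tips <- cbind(bio12 = tr1[seq_len(n)], bio17 = pmax(tr2[seq_len(n)], 0))
  rownames(tips) <- full_tree$tip.label
  occ <- simulate_occurrences(tips[surv, , drop = FALSE],
                              config$occurrence_k,
                              c(config$occurrence_noise_sd,
                                config$occurrence_noise_sd / 4),
                              seed = config$seed + 103)
  genus <- data.frame(genus = surv,
                      described = pmax(1L, stats::rpois(length(surv), 2) + 1L),
                      sampled = 1L)
  list(tree = tree, range_table = range_table, occurrences = occ,
       genus_totals = genus, history = hist, truth = pr$truth,
       full_tree = full_tree, traits = cbind(bio12 = tr1, bio17 = tr2),
       space = space, config = config, schedule = schedule, params = params)
}
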