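# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: the DEC oracle enumerates histories directly, the
# Yule oracle is the waiting-time closed form, and the Brownian root oracle
# is the GLS mean formula.

# exhaustive DEC(+J) likelihood: direct sum over internal-node states and
# cladogenetic daughter-start states, products of per-branch transition
# probabilities (no pruning, no shared code with dec_prune's recursion;
# per-node results are memoized for speed, which does not change the sum)
oracle_dec_loglik <- function(tree, tip_states, params, schedule, space) {
  n <- ape::Ntip(tree)
  S <- space$n_states
  ages <- node_ages(tree)
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  Pedge <- lapply(seq_len(nrow(tree$edge)), function(i)
    branch_transition_probs(space, params, schedule,
                            ages[tree$edge[i, 1]], ages[tree$edge[i, 2]]))
  edge_of <- function(ch) which(tree$edge[, 2] == ch)
  memo <- matrix(NA_real_, n + tree$Nnode, S)
  below <- function(v, s) {
    if (!is.na(memo[v, s])) return(memo[v, s])
    out <- if (v <= n) {
      as.numeric(s == tip_states[v])
    } else if (s == 1L) {
      0   # an extinct internal lineage yields no data
    } else {
      ch <- kids(v)
      P1 <- Pedge[[edge_of(ch[1])]]; P2 <- Pedge[[edge_of(ch[2])]]
      cd <- cladogenesis_distribution(space$states[[s]], params, space)
      tot <- 0
      for (r in seq_len(nrow(cd))) {
        f1 <- sum(vapply(1:S, function(s1)
          P1[cd$left[r], s1] * below(ch[1], s1), numeric(1)))
        f2 <- sum(vapply(1:S, function(s2)
          P2[cd$right[r], s2] * below(ch[2], s2), numeric(1)))
        tot <- tot + cd$prob[r] * f1 * f2
      }
      tot
    }
    memo[v, s] <<- out
    out
  }
  root <- n + 1L
  log(sum(vapply(2:S, function(s) below(root, s), numeric(1))))
}

# brute-force marginal posterior of the state at one internal node
oracle_dec_marginal <- function(tree, tip_states, params, schedule, space,
                                node) {
  n <- ape::Ntip(tree)
  S <- space$n_states
  ages <- node_ages(tree)
  kids <- function(v) tree$edge[tree$edge[, 1] == v, 2]
  below <- function(v, s, fs) {
    if (v == node && s != fs) return(0)
    if (v <= n) return(as.numeric(s == tip_states[v]))
    if (s == 1L) return(0)
    ch <- kids(v)
    cd <- cladogenesis_distribution(space$states[[s]], params, space)
    P1 <- branch_transition_probs(space, params, schedule, ages[v], ages[ch[1]])
    P2 <- branch_transition_probs(space, params, schedule, ages[v], ages[ch[2]])
    tot <- 0
    for (r in seq_len(nrow(cd))) {
      f1 <- sum(vapply(1:S, function(s1)
        P1[cd$left[r], s1] * below(ch[1], s1, fs), numeric(1)))
      f2 <- sum(vapply(1:S, function(s2)
        P2[cd$right[r], s2] * below(ch[2], s2, fs), numeric(1)))
      tot <- tot + cd$prob[r] * f1 * f2
    }
    tot
  }
  root <- n + 1L
  w <- vapply(1:S, function(fs) {
    if (fs == 1L) return(0)
    sum(vapply(2:S, function(s) below(root, s, fs), numeric(1)))
  }, numeric(1))
  w / sum(w)
}

# pure-birth log-likelihood from the waiting-time construction: splits at
# rate lambda on each extant lineage, conditioned on the crown age
oracle_yule_loglik <- function(tree, lambda) {
  n <- ape::Ntip(tree)
  ages <- node_ages(tree)
  x <- ages[n + seq_len(tree$Nnode)]
  x1 <- max(x)
  total_len <- 2 * x1 + sum(x[-which.max(x)])
  (n - 2) * log(lambda) - lambda * total_len
}

# GLS root estimate: (1' C^-1 y) / (1' C^-1 1) with C = vcv(tree)
oracle_gls_root <- function(tree, y) {
  C <- ape::vcv.phylo(tree)
  y <- y[rownames(C)]
  Ci <- solve(C)
  one <- rep(1, length(y))
  as.numeric((t(one) %*% Ci %*% y) / (t(one) %*% Ci %*% one))
}

# minimal forward Gillespie birth-death simulation from a crown pair,
# accepted when the extant count first reaches n; returns the crown age
oracle_bd_crown_age <- function(lambda, mu, n) {
  repeat {
    alive <- 2L; t <- 0
    repeat {
      rate <- alive * (lambda + mu)
      t <- t + stats::rexp(1, rate)
      if (stats::runif(1) < lambda / (lambda + mu)) alive <- alive + 1L
      else alive <- alive - 1L
      if (alive == 0L) break
      if (alive >= n) return(t)
    }
  }
}

# deterministic small fixture trees
balanced4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
caterpillar4 <- function() parse_newick("(((A:1,B:1):1,C:2):1,D:3);")

# ultrametric tree with a faster clade grafted in place of one background
# tip (stem repaired so all tips reach the present)
graft_shift_tree <- function(seed_bg, seed_cl, n_bg = 60, n_cl = 50,
                             la_bg = 0.1, la_cl = 0.3) {
  bg <- simulate_bd_tree(la_bg, 0.02, n_bg, seed = seed_bg)
  cl <- simulate_bd_tree(la_cl, 0.02, n_cl, seed = seed_cl)
  cl$tip.label <- paste0("c", seq_len(n_cl))
  host <- bg$tip.label[1]
  hnode <- match(host, bg$tip.label)
  stem_len <- bg$edge.length[bg$edge[, 2] == hnode]
  sc <- (0.75 * stem_len) / root_age(cl)
  if (sc < 1) cl$edge.length <- cl$edge.length * sc
  cl$root.edge <- 1e-8
  tr <- ape::bind.tree(bg, cl, where = hnode)
  cr <- ape::getMRCA(tr, cl$tip.label)
  dep <- ape::node.depth.edgelength(tr)
  target <- max(dep[match(setdiff(tr$tip.label, cl$tip.label), tr$tip.label)])
  gap <- target - dep[match(cl$tip.label[1], tr$tip.label)]
  e <- which(tr$edge[, 2] == cr)
  tr$edge.length[e] <- tr$edge.length[e] + gap
  stopifnot(tr$edge.length[e] > 0)
  list(tree = tr, clade_tips = cl$tip.label)
}
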