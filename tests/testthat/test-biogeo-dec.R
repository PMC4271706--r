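test_that("state space enumeration and ordering", {
  sp <- build_state_space(c("A", "B"), max_range = 2)
  expect_equal(sp$n_states, 4L)  # {A},{B},{A,B} + extinct
  expect_equal(sp$labels[1], "(extinct)")
  sp7 <- build_state_space(max_range = 4)
  expect_equal(sp7$n_states - 1L, 98L)  # C(7,1)+C(7,2)+C(7,3)+C(7,4)
  sp31 <- build_state_space(c("A", "B", "C"), max_range = 1)
  expect_equal(sp31$n_states - 1L, 3L)
  expect_error(build_state_space(c("A", "B"), max_range = 3), "max_range")
})

test_that("rate matrix follows the dispersal/extinction kernels", {
  sp <- build_state_space(c("A", "B"), max_range = 2)
  m <- matrix(c(1, 0.4, 0.7, 1), 2, 2)
  Q <- build_rate_matrix(sp, d = 0.3, e = 0.11, m = m)
  iA <- 2L  # {A} given deterministic ordering: extinct, {A}, {B}, {A,B}
  expect_equal(sp$labels[2:4], c("A", "B", "A+B"))
  expect_equal(Q[iA, 4], 0.3 * m[1, 2])   # {A} -> {A,B}
  expect_equal(Q[iA, 1], 0.11)            # {A} -> extinct
  expect_equal(Q[4, 2], 0.11)             # {A,B} -> {A}
  expect_equal(Q[1, 1], 0)                # extinct is absorbing
  # rows sum to zero for random parameters
  set.seed(42)
  for (i in 1:5) {
    mm <- matrix(runif(4), 2, 2)
    Qr <- build_rate_matrix(sp, runif(1), runif(1), mm)
    expect_lt(max(abs(rowSums(Qr))), 1e-12)
  }
  # d = 0 removes all expansions
  Q0 <- build_rate_matrix(sp, 0, 0.2, m)
  expect_equal(Q0[iA, 4], 0)
  expect_error(build_rate_matrix(sp, 1, 1, matrix(1, 3, 3)), "dimension")
})

test_that("branch propagators: identity, semigroup, epoch composition", {
  sp <- build_state_space(c("A", "B", "C"), max_range = 2)
  pars <- biogeo_params(0.2, 0.07, 0, "DEC")
  sched1 <- epoch_schedule(n_areas = 3)
  P0 <- branch_transition_probs(sp, pars, sched1, 5, 5)
  expect_equal(P0, diag(sp$n_states))
  # stratified schedule with identical multipliers equals one exponential
  m <- matrix(1, 3, 3)
  sched4 <- epoch_schedule(c(70, 45, 30, 5, 0), m, n_areas = 3)
  P_strat <- branch_transition_probs(sp, pars, sched4, 60, 2)
  P_one <- branch_transition_probs(sp, pars, sched1, 60, 2)
  expect_lt(max(abs(P_strat - P_one)), 1e-10)
  # crossing one boundary equals the two-segment composition
  m2 <- matrix(0.3, 3, 3); diag(m2) <- 1
  schedX <- epoch_schedule(c(30, 10, 0), list(m, m2), n_areas = 3)
  Pa <- branch_transition_probs(sp, pars, schedX, 20, 10)
  Pb <- branch_transition_probs(sp, pars, schedX, 10, 4)
  Pab <- branch_transition_probs(sp, pars, schedX, 20, 4)
  expect_lt(max(abs(Pa %*% Pb - Pab)), 1e-12)
  # rows stochastic
  expect_lt(max(abs(rowSums(Pab) - 1)), 1e-9)
  expect_true(all(Pab >= 0))
  expect_error(branch_transition_probs(sp, pars, sched1, 2, 5), "negative")
})

test_that("cladogenesis distributions match hand enumeration", {
  sp <- build_state_space(c("A", "B", "C"), max_range = 2)
  # singleton, j = 0: narrow sympatry only
  p0 <- biogeo_params(0.1, 0.1, 0, "DEC")
  cd <- cladogenesis_distribution("A", p0, sp)
  expect_equal(nrow(cd), 1L)
  expect_equal(cd$prob, 1)
  # {A,B}, j = 0: 4 subset-sympatry + 2 vicariance ordered pairs, each 1/6
  cd2 <- cladogenesis_distribution(c("A", "B"), p0, sp)
  expect_equal(nrow(cd2), 6L)
  expect_equal(cd2$prob, rep(1 / 6, 6))
  expect_equal(sum(cd2$prob), 1)
  # {A,B} with j = 0.5 and spare area C: founder pairs at weight 0.5 / 7
  pj <- biogeo_params(0.1, 0.1, 0.5, "DEC")
  cd3 <- cladogenesis_distribution(c("A", "B"), pj, sp)
  expect_equal(nrow(cd3), 8L)
  f <- cd3[cd3$left_label == "C" | cd3$right_label == "C", ]
  expect_equal(f$prob, rep(0.5 / 7, 2))
  expect_equal(sum(cd3$prob), 1)
  # DIVALIKE drops subset sympatry; BAYAREALIKE keeps only the copy
  cdd <- cladogenesis_distribution(c("A", "B"),
                                   biogeo_params(0.1, 0.1, 0, "DIVALIKE"), sp)
  expect_false(any(cdd$left_label == "A+B"))
  cdb <- cladogenesis_distribution(c("A", "B"),
                                   biogeo_params(0.1, 0.1, 0, "BAYAREALIKE"), sp)
  expect_equal(nrow(cdb), 1L)
  expect_equal(cdb$left_label, "A+B")
  expect_error(cladogenesis_distribution(integer(0), p0, sp), "extinct")
})

test_that("pruning likelihood equals exhaustive enumeration", {
  sp <- build_state_space(c("A", "B"), max_range = 2)
  sched <- epoch_schedule(n_areas = 2)
  trees <- list(parse_newick("(t1:1.5,t2:1.5);"),
                parse_newick("((t1:1,t2:1):1,t3:2);"),
                parse_newick("((t1:1,t2:1):1,(t3:0.5,t4:0.5):1.5);"))
  set.seed(99)
  for (tr in trees) {
    for (rep in 1:4) {
      pars <- biogeo_params(runif(1, 0.01, 0.6), runif(1, 0.01, 0.4),
                            runif(1, 0, 1.5), "DEC")
      st <- setNames(sample(2:4, ape::Ntip(tr), TRUE), tr$tip.label)
      ll <- dec_loglik(tr, st, pars, sched, sp)
      llo <- oracle_dec_loglik(tr, st, pars, sched, sp)
      expect_lt(abs(ll - llo), 1e-10)
    }
  }
})

test_that("zero-process likelihood, nesting, and invariances", {
  sp <- build_state_space(c("A", "B", "C"), max_range = 2)
  sched <- epoch_schedule(n_areas = 3)
  tr <- parse_newick("((t1:1,t2:1):1,t3:2);")
  # d = e = j = 0, all tips in one area: probability 1
  st <- setNames(rep(which(sp$labels == "A"), 3), tr$tip.label)
  expect_equal(dec_loglik(tr, st, biogeo_params(0, 0, 0, "DEC"), sched, sp), 0)
  # DEC+J with j = 0 equals DEC
  set.seed(5)
  for (i in 1:10) {
    pars <- biogeo_params(runif(1, 0.01, 0.5), runif(1, 0.01, 0.3), 0, "DEC")
    st <- setNames(sample(2:7, 3, TRUE), tr$tip.label)
    expect_lt(abs(dec_loglik(tr, st, pars, sched, sp) -
                  dec_loglik(tr, st, pars, sched, sp)), 1e-12)
  }
  # tip-order permutation invariance
  pars <- biogeo_params(0.2, 0.05, 0.3, "DEC")
  st <- setNames(c(2L, 4L, 6L), tr$tip.label)
  ll1 <- dec_loglik(tr, st, pars, sched, sp)
  ll2 <- dec_loglik(tr, st[c(3, 1, 2)], pars, sched, sp)
  expect_equal(ll1, ll2)
  # multiplier/d scale confound: m * c with d / c leaves likelihood unchanged
  cfac <- 0.25
  m1 <- matrix(0.8, 3, 3)
  schedA <- epoch_schedule(c(Inf, 0), m1, n_areas = 3)
  schedB <- epoch_schedule(c(Inf, 0), m1 * cfac, n_areas = 3)
  pA <- biogeo_params(0.1, 0.05, 0.2, "DEC")
  pB <- biogeo_params(0.1 / cfac, 0.05, 0.2, "DEC")
  expect_lt(abs(dec_loglik(tr, st, pA, schedA, sp) -
                dec_loglik(tr, st, pB, schedB, sp)), 1e-10)
})

test_that("marginal ancestral ranges match the enumeration posterior", {
  sp <- build_state_space(c("A", "B"), max_range = 2)
  sched <- epoch_schedule(n_areas = 2)
  tr <- parse_newick("((t1:1,t2:1):1,t3:2);")
  set.seed(17)
  for (rep in 1:3) {
    pars <- biogeo_params(runif(1, 0.05, 0.4), runif(1, 0.02, 0.2),
                          runif(1, 0, 1), "DEC")
    st <- setNames(sample(2:4, 3, TRUE), tr$tip.label)
    anc <- ancestral_ranges(tr, st, pars, sched, sp)
    pm <- attr(anc, "prob")
    expect_lt(max(abs(rowSums(pm) - 1)), 1e-9)
    for (nd in 4:5) {
      om <- oracle_dec_marginal(tr, st, pars, sched, sp, nd)
      expect_lt(max(abs(pm[nd, ] - om)), 1e-9)
    }
  }
  # degenerate process: every node certainly in the tip area
  st1 <- setNames(rep(2L, 3), tr$tip.label)
  anc0 <- ancestral_ranges(tr, st1, biogeo_params(0, 0, 0, "DEC"), sched, sp)
  expect_true(all(attr(anc0, "prob")[4:5, 2] == 1))
  expect_true(all(anc0$state == 2L))
})

test_that("fit_biogeo AIC arithmetic, weights, and comparison table", {
  expect_equal(2 * 2 - 2 * (-100), 204)  # AIC formula spot check
  sp <- build_state_space(c("A", "B"), max_range = 2)
  sched <- epoch_schedule(n_areas = 2)
  set.seed(3)
  tr <- simulate_bd_tree(0.4, 0.1, 12)
  h <- simulate_range_history(tr, biogeo_params(0.15, 0.02, 0.3, "DEC"),
                              sched, "A", seed = 8, space = sp)
  keep <- names(h$tip_states)[h$tip_states != 1L]
  prh <- prune_history(h)
  st <- h$tip_states[prh$tree$tip.label]
  cmp <- compare_biogeo_models(prh$tree, st, c("DEC", "DEC+J"), sched, sp)
  expect_equal(sum(cmp$weight), 1, tolerance = 1e-12)
  expect_equal(cmp$AIC, 2 * cmp$k - 2 * cmp$logLik)
  fit <- attr(cmp, "fits")[["DEC+J"]]
  expect_s3_class(fit, "biogeo_fit")
  expect_named(coef(fit), c("d", "e", "j"))
  expect_equal(AIC(fit), fit$AIC)   # logLik method wired into stats::AIC
  anc <- predict(fit)
  expect_s3_class(anc, "ancestral_range_table")
  expect_error(fit_biogeo(parse_newick("(a:1,b:1);"), st, "DEC"), "3 tips")
})
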