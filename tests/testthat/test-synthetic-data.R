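test_that("birth-death trees: forced structure, determinism, crown-age law", {
  tr <- simulate_bd_tree(1, 0, 2, seed = 1)
  expect_equal(ape::Ntip(tr), 2L)
  expect_true(ape::is.ultrametric(tr))
  expect_identical(write_newick(simulate_bd_tree(0.3, 0.1, 10, seed = 7)),
                   write_newick(simulate_bd_tree(0.3, 0.1, 10, seed = 7)))
  expect_error(simulate_bd_tree(0.3, 0.1, 1), "at least 2")
  expect_error(simulate_bd_tree(0.1, 0.2, 10), "birth_rate > death_rate")
  # Monte-Carlo crown-age check against an independent forward simulator
  set.seed(123)
  n <- 40
  mine <- replicate(120, root_age(simulate_bd_tree(0.2, 0.1, n)))
  oracle <- replicate(120, oracle_bd_crown_age(0.2, 0.1, n))
  expect_lt(abs(mean(mine) - mean(oracle)) / mean(oracle), 0.25)
})

test_that("range-history simulation: degenerate process, determinism, replay", {
  sp <- build_state_space(c("SA", "CA", "Me"), max_range = 2)
  sched <- epoch_schedule(n_areas = 3)
  tr <- simulate_bd_tree(0.3, 0.05, 20, seed = 2)
  h0 <- simulate_range_history(tr, biogeo_params(0, 0, 0, "DEC"), sched,
                               "SA", seed = 3, space = sp)
  expect_true(all(h0$tip_states == which(sp$labels == "SA")))
  expect_equal(nrow(h0$events), 0L)
  h1 <- simulate_range_history(tr, biogeo_params(0.08, 0.02, 0.2, "DEC"),
                               sched, "SA", seed = 11, space = sp)
  h2 <- simulate_range_history(tr, biogeo_params(0.08, 0.02, 0.2, "DEC"),
                               sched, "SA", seed = 11, space = sp)
  expect_identical(h1$events, h2$events)
  expect_identical(h1$node_states, h2$node_states)
  expect_true(replay_history(h1))
  # event times live inside their branch's age interval
  if (nrow(h1$events) > 0) {
    ages <- node_ages(tr)
    pv <- tr$edge[match(h1$events$child, tr$edge[, 2]), 1]
    expect_true(all(h1$events$age >= ages[h1$events$child] - 1e-9))
    expect_true(all(h1$events$age <= ages[pv] + 1e-9))
  }
  expect_error(simulate_range_history(tr, biogeo_params(0.1, 0, 0, "DEC"),
                                      sched, character(0), space = sp))
})

test_that("per-branch gain counts match the dispersal kernel rates", {
  # single lineage, one long branch: empirical gain rate from {A} at d * m
  sp <- build_state_space(c("A", "B", "C"), max_range = 2)
  m <- matrix(c(1, 0.5, 0.2, 0.5, 1, 1, 0.2, 1, 1), 3, 3)
  sched <- epoch_schedule(c(Inf, 0), m, n_areas = 3)
  tr <- parse_newick("(x:4,y:4);")
  d <- 0.05
  pars <- biogeo_params(d, 0, 0, "DEC")
  set.seed(31)
  first_gain <- table(unlist(lapply(1:600, function(i) {
    h <- simulate_range_history(tr, pars, sched, "A", seed = 7000 + i,
                                space = sp)
    ev <- h$events[h$events$type == "gain", ]
    if (nrow(ev)) ev$area[which.max(ev$age)] else NULL
  })))
  # gains out of {A}: to B at d*m[A,B] = 0.025, to C at d*m[A,C] = 0.01
  ratio <- first_gain[["2"]] / first_gain[["3"]]
  expect_gt(ratio, (0.025 / 0.01) * 0.7)
  expect_lt(ratio, (0.025 / 0.01) * 1.4)
})

test_that("Brownian trait simulation obeys the variance law", {
  tr <- parse_newick("(a:3,b:2);")
  # degenerate diffusion collapses to the root value
  v0 <- simulate_bm_traits(tr, 1e-12, 5, seed = 1)
  expect_lt(max(abs(v0 - 5)), 1e-4)
  expect_identical(simulate_bm_traits(tr, 10, 0, seed = 4),
                   simulate_bm_traits(tr, 10, 0, seed = 4))
  set.seed(5)
  sig2 <- 7
  diffs <- replicate(8000, {
    v <- simulate_bm_traits(tr, sig2, 0)
    v[1] - v[2]
  })
  expect_lt(abs(var(diffs) - sig2 * 5) / (sig2 * 5), 0.05)
  # clade shift lands on the targeted branch
  tr4 <- balanced4()
  vs <- simulate_bm_traits(tr4, 1e-10, 0, seed = 9,
                           shifts = data.frame(node = 6, delta = -100))
  expect_lt(max(abs(vs[c("A", "B")] + 100)), 1e-3)
  expect_lt(max(abs(vs[c("C", "D")])), 1e-3)
})

test_that("occurrence records scatter around tip values as configured", {
  tips <- c(a = 1500, b = 60)
  occ0 <- simulate_occurrences(tips, k = 3, noise_sd = 0, seed = 2)
  expect_equal(nrow(occ0), 6L)
  expect_true(all(occ0$trait1[occ0$species == "a"] == 1500))
  occ1 <- simulate_occurrences(tips, k = 1, noise_sd = 5, seed = 2)
  m1 <- species_climate_means(occ1)
  expect_equal(m1$trait1[m1$species == "a"],
               occ1$trait1[occ1$species == "a"])
  # CLT bound: species mean within 3 SE of truth almost always
  set.seed(12)
  hits <- replicate(300, {
    occ <- simulate_occurrences(c(s = 1000), k = 100, noise_sd = 50)
    abs(mean(occ$trait1) - 1000) <= 3 * 50 / sqrt(100)
  })
  expect_gte(mean(hits), 0.99 - 0.02)
  expect_error(simulate_occurrences(tips, k = 0, noise_sd = 1), "at least 1")
})

test_that("jittered ensembles keep dated-tree invariants and stay unbiased", {
  tr <- simulate_bd_tree(0.25, 0.05, 25, seed = 6)
  ens0 <- make_tree_ensemble(tr, 4, age_jitter_sd = 0, seed = 1)
  for (t2 in ens0) expect_identical(write_newick(t2), write_newick(tr))
  ens <- make_tree_ensemble(tr, 30, age_jitter_sd = 0.05, seed = 2)
  for (t2 in ens) {
    expect_silent(validate_dated_tree(t2))
    expect_true(all(t2$edge.length > 0))
  }
  roots <- vapply(make_tree_ensemble(tr, 400, 0.05, seed = 3), root_age,
                  numeric(1))
  expect_lt(abs(mean(roots) - root_age(tr)) / root_age(tr), 0.02)
  expect_error(make_tree_ensemble(tr, 0, 0.05), "at least 1")
})

test_that("two-rate dispersal scenarios carry a detectable rate increase", {
  # epoch multipliers raised after the boundary must yield more true
  # expansion events per Myr after than before, in most replicates
  sp <- build_state_space(c("SA", "Me"), max_range = 2)
  m_lo <- matrix(0.1, 2, 2); diag(m_lo) <- 1
  m_hi <- matrix(1, 2, 2)
  sched <- epoch_schedule(c(Inf, 24, 0), list(m_lo, m_hi), n_areas = 2)
  pars <- biogeo_params(0.05, 0.01, 0, "DEC")
  tr <- simulate_bd_tree(0.12, 0.02, 60, seed = 13)
  ages <- node_ages(tr)
  span_before <- root_age(tr) - 24
  wins <- 0L; nrep <- 40L
  for (i in seq_len(nrep)) {
    h <- simulate_range_history(tr, pars, sched, "SA", seed = 9000 + i,
                                space = sp)
    ev <- true_focal_events(h, "Me")
    ex <- ev$event_age[ev$type == "expansion"]
    rb <- sum(ex > 24) / span_before
    ra <- sum(ex <= 24) / 24
    if (ra > rb) wins <- wins + 1L
  }
  # one-sided sign test: after-rate exceeds before-rate more often than chance
  expect_lt(stats::pbinom(wins - 1, nrep, 0.5, lower.tail = FALSE), 0.05)
})

test_that("simulate_dataset wires the generators together with truth", {
  cfg <- simulation_config(n_tips = 30, seed = 42, occurrence_k = 4)
  ds <- simulate_dataset(cfg)
  expect_true(all(rownames(ds$range_table) == ds$tree$tip.label))
  expect_true(all(rowSums(ds$range_table) >= 1))
  expect_s3_class(ds$truth, "ancestral_range_table")
  expect_equal(nrow(ds$occurrences), 4L * ape::Ntip(ds$tree))
  ds2 <- simulate_dataset(cfg)
  expect_identical(write_newick(ds$tree), write_newick(ds2$tree))
  expect_identical(ds$range_table, ds2$range_table)
})
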