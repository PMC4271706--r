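test_that("birth-death likelihood matches the pure-birth closed form", {
  set.seed(41)
  for (i in 1:10) {
    tr <- simulate_bd_tree(0.3, 0, sample(5:40, 1))
    la <- runif(1, 0.05, 0.5)
    expect_lt(abs(bd_loglik(tr, la, 0, f = 1) - oracle_yule_loglik(tr, la)),
              1e-8)
  }
  tr <- simulate_bd_tree(0.3, 0.1, 20, seed = 2)
  # invariant to tip relabeling
  tr2 <- tr; tr2$tip.label <- rev(tr2$tip.label)
  expect_equal(bd_loglik(tr, 0.3, 0.1, 0.8), bd_loglik(tr2, 0.3, 0.1, 0.8))
  # continuity in the sampling fraction
  expect_lt(abs(bd_loglik(tr, 0.3, 0.1, 1) - bd_loglik(tr, 0.3, 0.1, 0.999)) /
            abs(bd_loglik(tr, 0.3, 0.1, 1)), 0.001)
  expect_error(bd_loglik(tr, -1, 0.1), "positive")
})

test_that("fit_bd agrees with the reference implementation on Yule trees", {
  # the ML extinction rate on Yule reconstructed trees is notoriously
  # dispersed (roughly half the trees give mu-hat well above 0), so the
  # check is concordance with ape::birthdeath plus boundary mass at mu = 0
  set.seed(51)
  ratios <- numeric(0)
  for (i in 1:12) {
    tr <- simulate_bd_tree(0.25, 0, 60)
    fit <- fit_bd(tr, f = 1)
    ref <- tryCatch(suppressWarnings(ape::birthdeath(tr)$para),
                    error = function(e) NULL)
    if (!is.null(ref)) {
      la_ref <- ref[["b-d"]] / (1 - ref[["d/b"]])
      mu_ref <- la_ref * ref[["d/b"]]
      expect_lt(abs(fit$lambda - la_ref), 0.05 * la_ref + 1e-3)
      expect_lt(abs(fit$mu - mu_ref), 0.05 * la_ref + 1e-3)
    }
    ratios <- c(ratios, fit$mu / fit$lambda)
  }
  expect_gte(mean(ratios < 1e-3), 0.25)  # a solid share sit at the boundary
  expect_error(fit_bd(parse_newick("(a:1,b:1);")), "at least 3")
})

test_that("shift scan accepts nothing at an infinite threshold", {
  tr <- simulate_bd_tree(0.25, 0.05, 40, seed = 3)
  sc <- scan_shifts(tr, delta_aic = Inf)
  expect_equal(nrow(sc$shifts), 0L)
  expect_gt(sc$n_candidates, 0L)
})

test_that("dispersal vs diversification comparison reports the headline ratio", {
  out <- compare_dispersal_vs_diversification(c(1.7, 1.7), c(0.1, 0.3),
                                              post_inflection_rate = 1.7)
  expect_equal(out$ratio, 1.7 / 0.3, tolerance = 1e-12)
  expect_equal(out$ratio_nearest_integer, 6)
  same <- compare_dispersal_vs_diversification(c(0.3), c(0.3))
  expect_equal(same$ratio, 1)
  expect_error(compare_dispersal_vs_diversification(c(1), numeric(0)),
               "empty")
})

test_that("MPD partition: worked example, flags, invariances", {
  tr <- balanced4()   # ((A:1,B:1):1,(C:1,D:1):1);
  asg <- c(A = 1, B = 1, C = 2, D = 2)
  pd <- mpd_partition(tr, asg)
  expect_equal(pd$mpd_in_situ, 2.0)
  expect_equal(pd$mpd_between, 4.0)
  expect_equal(pd$mpd_in_situ_half, 1.0)
  # relabeling introductions and reordering tips changes nothing
  pd2 <- mpd_partition(tr, c(D = "x", C = "x", B = "q", A = "q"))
  expect_equal(pd2$mpd_in_situ, pd$mpd_in_situ)
  expect_equal(pd2$mpd_between, pd$mpd_between)
  one <- mpd_partition(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_true(is.na(one$mpd_between))
  solo <- mpd_partition(tr, c(A = 1, B = 2, C = 3, D = 4))
  expect_true(is.na(solo$mpd_in_situ))
  # constructed tree where within-MRCAs are younger than between-MRCAs
  expect_lt(pd$mpd_in_situ, pd$mpd_between)
  expect_error(mpd_partition(tr, c(Z = 1, A = 1)), "not in tree")
})

test_that("chi-squared sampling-bias test: arithmetic, errors, permutation check", {
  o <- c(wet = 8, dry = 12); e <- c(wet = 10, dry = 10)
  res <- chi2_sampling_bias(o, e)
  expect_equal(res$statistic, 0.8)
  expect_equal(res$df, 1L)
  ident <- chi2_sampling_bias(e, e)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p_value, 1)
  expect_error(chi2_sampling_bias(c(a = 1), c(b = 1)), "categories")
  expect_error(chi2_sampling_bias(o, c(wet = 0, dry = 20)), "pool")
  # p-value concords with a multinomial Monte-Carlo null
  set.seed(61)
  oo <- c(a = 30, b = 14, c = 16)
  ee <- c(a = 24, b = 18, c = 18)
  res2 <- chi2_sampling_bias(oo, ee)
  probs <- ee / sum(ee)
  sims <- stats::rmultinom(4000, sum(oo), probs)
  stat_sim <- colSums((sims - ee)^2 / ee)
  p_mc <- mean(stat_sim >= res2$statistic)
  expect_lt(abs(p_mc - res2$p_value), 0.05)
})

test_that("introduction assignment picks the most recent expansion on the path", {
  sp <- build_state_space(c("SA", "Me"), max_range = 2)
  tr <- parse_newick("(((A:5,B:5):10,C:15):10,D:25);")
  ages <- node_ages(tr)
  ev <- data.frame(type = c("expansion", "expansion"),
                   parent = c(6L, 6L), child = c(7L, 3L),
                   stem_age = c(25, 25), crown_age = c(15, 0),
                   parent_range = "SA", child_range = "SA+Me",
                   event_age = c(25, 25), stringsAsFactors = FALSE)
  asg <- assign_introductions(tr, ev, c("A", "B", "C"))
  expect_equal(unname(asg[c("A", "B")]), c(7L, 7L))
  expect_equal(unname(asg["C"]), 3L)
})

test_that("a three-fold speciation shift in a large clade is detected", {
  hits <- vapply(1:10, function(i) {
    g <- graft_shift_tree(1300 + i, 1400 + i)
    sh <- scan_shifts(g$tree)
    if (nrow(sh$shifts) == 0L) return(FALSE)
    any(vapply(sh$shifts$node, function(v) {
      tt <- g$tree$tip.label[biomepool:::descendant_tips(g$tree, v)]
      length(intersect(tt, g$clade_tips)) /
        length(union(tt, g$clade_tips)) > 0.5
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("MPD within-introduction weighting modes differ as documented", {
  tr <- parse_newick("((A:1,B:1):2,((C:1,D:1):1,E:2):1);")
  asg <- c(A = 1, B = 1, C = 2, D = 2, E = 2)
  pooled <- mpd_partition(tr, asg, weighting = "pairs")
  byintro <- mpd_partition(tr, asg, weighting = "introductions")
  # intro 1 has one pair (d = 2); intro 2 has pairs 2, 4, 4 (mean 10/3)
  expect_equal(pooled$mpd_in_situ, (2 + 2 + 4 + 4) / 4)
  expect_equal(byintro$mpd_in_situ, (2 + 10 / 3) / 2)
  expect_equal(pooled$mpd_between, byintro$mpd_between)
})
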