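test_that("species climate means aggregate and reject bad rows", {
  occ <- data.frame(species = c("a", "a", "b", "c"),
                    bio12 = c(100, 300, 1500, "oops"),
                    bio17 = c(10, 30, 60, 5))
  expect_warning(prof <- species_climate_means(occ), "rejected")
  expect_equal(prof$bio12[prof$species == "a"], 200)
  expect_equal(prof$n_records[prof$species == "a"], 2L)
  expect_false("c" %in% prof$species)
  one <- species_climate_means(data.frame(species = "z", bio12 = 1500,
                                          bio17 = 60))
  expect_equal(unname(unlist(one[1, c("bio12", "bio17")])), c(1500, 60))
})

test_that("group labels follow the endemic/widespread/non-focal rules", {
  tab <- rbind(sp1 = c(SA = 0, Me = 1), sp2 = c(SA = 1, Me = 1),
               sp3 = c(SA = 1, Me = 0))
  g <- assign_groups(tab, "Me")
  expect_equal(as.character(g[c("sp1", "sp2", "sp3")]),
               c("endemic", "widespread", "non_focal"))
  bad <- rbind(tab, sp4 = c(SA = 0, Me = 0))
  expect_error(assign_groups(bad, "Me"), "sp4")
})

test_that("PGLS on a star tree reduces to ordinary least squares", {
  n <- 30
  star <- ape::stree(n, "star")
  star$edge.length <- rep(1, n)
  star$tip.label <- paste0("s", 1:n)
  set.seed(8)
  grp <- factor(setNames(sample(c("non_focal", "endemic", "widespread"),
                                n, TRUE),
                         star$tip.label),
                levels = c("non_focal", "endemic", "widespread"))
  y <- rnorm(n, 100, 10)
  prof <- data.frame(species = star$tip.label, bio12 = y)
  fit <- pgls_group_test(star, prof, grp, "bio12")
  ols <- lm(y ~ grp)
  expect_lt(max(abs(fit$coefficients$estimate - coef(ols))), 1e-8)
  # group absent: explicit error
  grp2 <- factor(setNames(rep("endemic", n), star$tip.label),
                 levels = levels(grp))
  expect_error(pgls_group_test(star, prof, grp2, "bio12"), "group")
})

test_that("Brownian ML reconstruction: midpoints, constants, GLS oracle", {
  tr <- parse_newick("(a:1,b:1);")
  fit <- bm_ancestral_ml(tr, c(a = 1000, b = 2000))
  expect_equal(unname(fit$ace[3]), 1500)
  trc <- balanced4()
  fc <- bm_ancestral_ml(trc, c(A = 7, B = 7, C = 7, D = 7))
  expect_true(all(abs(fc$ace - 7) < 1e-10))
  expect_equal(fc$sigma2, 0)
  set.seed(14)
  for (i in 1:10) {
    tr <- simulate_bd_tree(0.4, 0.1, sample(4:10, 1))
    y <- setNames(rnorm(ape::Ntip(tr), 50, 20), tr$tip.label)
    fit <- bm_ancestral_ml(tr, y)
    expect_lt(abs(fit$root_state - oracle_gls_root(tr, y)), 1e-6)
    # invariances: tip order, and adding a constant shifts all estimates
    fit_perm <- bm_ancestral_ml(tr, y[sample(names(y))])
    expect_lt(max(abs(fit$ace - fit_perm$ace)), 1e-8)
    fit_shift <- bm_ancestral_ml(tr, y + 123)
    expect_lt(max(abs(fit_shift$ace - (fit$ace + 123))), 1e-6)
  }
  expect_error(bm_ancestral_ml(balanced4(), c(A = 1, B = 2, C = 3)),
               "without values")
})

test_that("ancestral estimate error shrinks with tip count", {
  # trees rescaled to unit depth so depth does not confound the comparison;
  # errors taken over all internal nodes
  set.seed(22)
  rmse_at <- function(n) {
    errs <- unlist(lapply(1:30, function(i) {
      tr <- simulate_bd_tree(0.3, 0.05, n)
      tr$edge.length <- tr$edge.length / root_age(tr)
      v <- simulate_bm_traits(tr, 100, 0)
      fit <- bm_ancestral_ml(tr, v[seq_len(n)])
      ints <- n + seq_len(tr$Nnode)
      fit$ace[ints] - v[ints]
    }))
    c(bias = median(errs), rmse = sqrt(mean(errs^2)))
  }
  r25 <- rmse_at(25); r50 <- rmse_at(50); r100 <- rmse_at(100)
  expect_lt(abs(r25[["bias"]]), 2)          # near-zero median bias (sd ~ 10)
  expect_lt(r50[["rmse"]], r25[["rmse"]])
  expect_lt(r100[["rmse"]], r25[["rmse"]])
})

test_that("Bayesian reconstruction concords with ML under flat priors", {
  set.seed(33)
  for (i in 1:5) {
    tr <- simulate_bd_tree(0.4, 0.05, 8)
    y <- setNames(rnorm(8, 0, 5), tr$tip.label)
    ml <- bm_ancestral_ml(tr, y)
    bb <- bm_ancestral_bayes(tr, y, n_iter = 2000, seed = 100 + i)
    psd <- apply(bb$ci, 1, function(ci) (ci[2] - ci[1]) / (2 * 1.96))
    ints <- 8 + seq_len(tr$Nnode)
    expect_true(all(abs(bb$mean - ml$ace[ints]) <= 2.5 * pmax(psd, 1e-6)))
  }
  bb1 <- bm_ancestral_bayes(balanced4(), c(A = 1, B = 1, C = 1, D = 1),
                            n_iter = 500, seed = 1)
  expect_lt(max(abs(bb1$mean - 1)), 0.2)
  b2 <- bm_ancestral_bayes(balanced4(), c(A = 1, B = 3, C = 2, D = 0),
                           n_iter = 500, seed = 9)
  b3 <- bm_ancestral_bayes(balanced4(), c(A = 1, B = 3, C = 2, D = 0),
                           n_iter = 500, seed = 9)
  expect_identical(b2$mean, b3$mean)
})

test_that("threshold crossings interpolate linearly and respect the rules", {
  # chain a -> b: parent value 2000 at age 30, child 1600 at age 20
  tr <- parse_newick("(x:30,(y:20,z:20):10);")
  fit <- list(ace = c(x = 2500, y = 1600, z = 1600, N4 = 2000, N5 = 1600))
  # hand-build: root N4 age 30 value 2000; N5 age 20 value 1600
  fit$ace <- c(2500, 1600, 1600, 2000, 1600)
  cr <- threshold_crossing_age(tr, fit, target = 5L,
                               spec = threshold_spec("bio12", 1800))
  expect_equal(cr$crossing_age, 25.0)
  # root already below: crossing at root age
  fit2 <- list(ace = c(1500, 1400, 1400, 1500, 1450))
  cr2 <- threshold_crossing_age(tr, fit2, 5L, threshold_spec("bio12", 1800))
  expect_equal(cr2$crossing_age, root_age(tr))
  # never below: none
  fit3 <- list(ace = c(2500, 2400, 2400, 2500, 2450))
  cr3 <- threshold_crossing_age(tr, fit3, 5L, threshold_spec("bio12", 1800))
  expect_true(is.na(cr3$crossing_age))
  expect_error(threshold_crossing_age(tr, fit, 99L,
                                      threshold_spec("bio12", 1800)),
               "target")
  expect_error(threshold_spec("bio12", -5), "positive")
})

test_that("lag classification follows the sign and same-branch rules", {
  restriction <- list(child = 5L, event_age = 18, stem_age = 18, crown_age = 12)
  mk_cross <- function(age, branch) {
    structure(list(target = 5L, crossing_age = age, branch = branch,
                   recrossings = 0L,
                   spec = threshold_spec("bio12", 1800)),
              class = "crossing_record")
  }
  lag1 <- lag_time(restriction, mk_cross(40, 3L))
  expect_equal(lag1$lag, 22)
  expect_equal(lag1$class, "pre_adapted")
  lag2 <- lag_time(restriction, mk_cross(15, 5L))   # on the restriction branch
  expect_equal(lag2$class, "concurrent")
  lag3 <- lag_time(restriction, mk_cross(10, 7L))
  expect_equal(lag3$lag, -8)
  expect_equal(lag3$class, "in_situ")
  lag4 <- lag_time(restriction, mk_cross(NA_real_, NA_integer_))
  expect_equal(lag4$class, "in_situ")
  expect_true(is.na(lag4$lag))
  bad <- restriction; bad$child <- 6L
  expect_error(lag_time(bad, mk_cross(40, 3L)), "different lineages")
})
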