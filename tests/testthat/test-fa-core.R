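test_that("constant data yield all-zero mean squares and zero FA10a", {
  d <- make_block(array(7, dim = c(3, 2, 2)))
  tbl <- fa_anova(d)
  expect_equal(unname(tbl$ms), rep(0, 4))
  fit <- fa_fit(d)
  expect_identical(fit$fa10a, 0)
  expect_false(fit$negative_flag)
})

test_that("mean squares match the loop oracle and anova(lm())", {
  set.seed(314)
  for (k in 1:30) {
    n <- sample(2:8, 1); r <- sample(2:3, 1)
    d <- random_block_df(n, r)
    tbl <- fa_anova(d)
    orc <- oracle_anova(d)
    expect_equal(tbl$ms, orc$ms, tolerance = 1e-10)
    # SS conservation against the total corrected SS
    expect_equal(sum(tbl$ss), sum((d$length - mean(d$length))^2),
                 tolerance = 1e-9)
  }
  # independent cross-check against the standard linear-model ANOVA
  d <- random_block_df(6, 3)
  lf <- anova(lm(length ~ side * individual, data = d))
  ms <- setNames(lf[["Mean Sq"]],
                 c("side", "individual", "interaction", "residual"))
  expect_equal(fa_anova(d)$ms, ms, tolerance = 1e-12)
})

test_that("mean squares are location invariant and scale equivariant", {
  set.seed(9)
  d <- random_block_df(5, 2)
  tbl <- fa_anova(d)
  d_shift <- d; d_shift$length <- d$length + 42
  expect_equal(fa_anova(d_shift)$ms, tbl$ms, tolerance = 1e-9)
  d_scaled <- d; d_scaled$length <- d$length * 3
  tbl_s <- fa_anova(d_scaled)
  expect_equal(tbl_s$ms, tbl$ms * 9, tolerance = 1e-9)
  expect_equal(fa_fit(d_scaled)$fa10a, fa_fit(d)$fa10a * 9, tolerance = 1e-9)
  # F statistics and p-values of a comparison are scale free
  e <- random_block_df(5, 2)
  c1 <- compare_fa(fa_fit(d), fa_fit(e))
  e_scaled <- e; e_scaled$length <- e$length * 3
  c2 <- compare_fa(fa_fit(d_scaled), fa_fit(e_scaled))
  expect_equal(c2$f, c1$f, tolerance = 1e-12)
  expect_equal(c2$p, c1$p, tolerance = 1e-12)
})

test_that("FA10a is (MS_int - MS_res)/r and negatives are flagged, not clamped", {
  set.seed(11)
  d <- random_block_df(6, 2)
  fit <- fa_fit(d)
  tbl <- fit$anova
  expect_equal(fit$fa10a,
               unname(tbl$ms["interaction"] - tbl$ms["residual"]) / 2)
  expect_equal(fit$me_variance, unname(tbl$ms["residual"]))

  # additive cell means (zero interaction) + replicate noise: raw FA10a < 0
  ind <- c(10, 20, 30); side <- c(0, 5)
  cells <- outer(ind, side, "+")
  vals <- array(c(cells + 1, cells - 1), dim = c(3, 2, 2))
  fit_neg <- fa_fit(make_block(vals))
  expect_true(fit_neg$negative_flag)
  expect_lt(fit_neg$fa10a, 0)
  expect_equal(fit_neg$anova$ms[["interaction"]], 0)
})

test_that("directional asymmetry reports the planted side offset", {
  set.seed(21)
  d <- random_block_df(8, 2)
  delta <- 3.5
  d$length <- d$length + ifelse(d$side == "R", delta, 0)
  fit <- fa_fit(d)
  d0 <- d; d0$length <- d$length - ifelse(d$side == "R", delta, 0)
  expect_equal(fit$da$delta, fa_fit(d0)$da$delta + delta, tolerance = 1e-9)

  # swapping side labels flips the sign of DA but not F, and FA10a is invariant
  swapped <- d
  swapped$side <- ifelse(d$side == "L", "R", "L")
  fs <- fa_fit(swapped)
  expect_equal(fs$da$delta, -fit$da$delta, tolerance = 1e-12)
  expect_equal(fs$da$f, fit$da$f, tolerance = 1e-12)
  expect_equal(fs$fa10a, fit$fa10a, tolerance = 1e-12)
})

test_that("compare_fa satisfies identity and reciprocity", {
  a <- fa_fit(simulate_sample(n = 8, sigma_fa = 8, sigma_me = 1, seed = 33,
                              genotype = "a"))
  b <- fa_fit(simulate_sample(n = 8, sigma_fa = 8, sigma_me = 1, seed = 34,
                              genotype = "b"))
  self <- compare_fa(a, a)
  expect_equal(self$f, 1)
  expect_equal(self$p, 1)
  expect_equal(self$fold_change, 1)
  ab <- compare_fa(a, b); ba <- compare_fa(b, a)
  expect_equal(ab$fold_change * ba$fold_change, 1, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_true(ab$direction != ba$direction)
})

test_that("a non-positive reference FA10a voids the fold change but not the test", {
  ind <- c(10, 20, 30); side <- c(0, 5)
  cells <- outer(ind, side, "+")
  neg <- fa_fit(make_block(array(c(cells + 1, cells - 1), dim = c(3, 2, 2))))
  set.seed(44)
  a <- fa_fit(random_block_df(3, 2))
  cmp <- compare_fa(a, neg)
  expect_true(cmp$fold_flag)
  expect_true(is.na(cmp$fold_change))
  expect_false(is.na(cmp$p))
  expect_gt(cmp$ms_ratio, 0)
  expect_error(compare_fa(a, neg, mode = "fa10a"), "positive")
})

test_that("the fa10a-ratio mode tests the index ratio directly", {
  set.seed(55)
  a <- fa_fit(simulate_sample(n = 12, sigma_fa = 6, seed = 1, genotype = "a"))
  b <- fa_fit(simulate_sample(n = 12, sigma_fa = 3, seed = 2, genotype = "b"))
  cmp <- compare_fa(a, b, mode = "fa10a")
  expect_equal(cmp$f, a$fa10a / b$fa10a)
  expect_equal(cmp$fold_change, cmp$f)
})

test_that("fa_fit methods are coherent", {
  s <- simulate_sample(n = 8, r = 3, seed = 77)
  fit <- fa_fit(s)
  expect_named(coef(fit), c("fa10a", "me_variance", "da_delta", "mean_size",
                            "interindividual_variance"))
  expect_equal(fitted(fit) + residuals(fit), s$data$length, tolerance = 1e-12)
  # residuals average to zero within every (individual, side) cell
  cellmeans <- tapply(residuals(fit),
                      paste(s$data$individual, s$data$side), mean)
  expect_true(all(abs(cellmeans) < 1e-10))
  sims <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sims, 2L)
  expect_equal(sims[[1]]$n, fit$n)
  expect_equal(sims[[1]]$r, fit$r)
  expect_output(print(summary(fit)), "FA10a")
})

test_that("fa_anova rejects designs where error is not separable", {
  d <- make_block(array(rnorm(6, 10), dim = c(3, 2, 1)))
  expect_error(fa_anova(d), "not separable")
  one <- make_block(array(rnorm(4, 10), dim = c(1, 2, 2)))
  expect_error(fa_anova(one), "at least 2 individuals")
})
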