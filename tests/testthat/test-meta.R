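test_that("single effect pools to itself with zero heterogeneity", {
  f <- re_meta(z ~ 1, vi = v, data = data.frame(z = 0.4, v = 0.02))
  expect_equal(f$pooled_z, 0.4)
  expect_equal(f$tau2, 0)
  expect_equal(f$Q, 0)
  expect_equal(f$se_z, sqrt(0.02))
})

test_that("identical effects give Q = 0, I2 = 0 and the common value", {
  d <- data.frame(z = rep(0.3, 5), v = rep(0.01, 5))
  f <- re_meta(z ~ 1, vi = v, data = d)
  expect_equal(f$Q, 0)
  expect_equal(f$I2, 0)
  expect_equal(f$pooled_z, 0.3)
  h <- heterogeneity(d$z, d$v)
  expect_equal(h$Q, 0)
  expect_equal(h$p_Q, 1)
  expect_equal(h$I2, 0)
})

test_that("DL pooling equals the naive textbook implementation", {
  set.seed(11)
  for (i in 1:1000) {
    k <- sample(2:12, 1)
    v <- runif(k, 0.005, 0.2)
    z <- rnorm(k, 0.2, 0.3)
    f <- re_meta(z ~ 1, vi = v, data = data.frame(z = z, v = v))
    o <- dl_naive(z, v)
    expect_equal(f$pooled_z, o$pooled, tolerance = 1e-10)
    expect_equal(f$tau2, o$tau2, tolerance = 1e-10)
    expect_equal(f$Q, o$Q, tolerance = 1e-10)
    expect_equal(f$se_z, o$se, tolerance = 1e-10)
    # pooled estimate stays inside the convex hull of the effects
    expect_gte(f$pooled_z, min(z) - 1e-12)
    expect_lte(f$pooled_z, max(z) + 1e-12)
    expect_gte(f$tau2, 0)
    expect_true(f$I2 >= 0 && f$I2 < 100)
  }
})

test_that("pooling and meta-regression agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(12)
  k <- 8
  v <- 1 / (sample(17:56, k) - 3)
  z <- rnorm(k, 0.3, 0.2)
  x <- rnorm(k)
  f <- re_meta(z ~ 1, vi = v, data = data.frame(z = z))
  r <- metafor::rma(yi = z, vi = v, method = "DL")
  expect_equal(f$pooled_z, unname(coef(r)), tolerance = 1e-10)
  expect_equal(f$tau2, r$tau2, tolerance = 1e-10)
  expect_equal(f$I2, r$I2, tolerance = 1e-8)
  fm <- re_meta(z ~ x, vi = v, data = data.frame(z = z, x = x))
  rm_ <- metafor::rma(yi = z, vi = v, mods = ~ x, method = "DL")
  expect_equal(unname(fm$b), unname(coef(rm_)), tolerance = 1e-10)
  expect_equal(fm$QM, rm_$QM, tolerance = 1e-10)
  expect_equal(fm$tau2, rm_$tau2, tolerance = 1e-10)
  frml <- re_meta(z ~ 1, vi = v, data = data.frame(z = z), method = "REML")
  rreml <- metafor::rma(yi = z, vi = v, method = "REML")
  expect_equal(frml$tau2, rreml$tau2, tolerance = 1e-3)
})

test_that("intercept-only meta-regression reduces to the plain pool", {
  set.seed(13)
  v <- runif(8, 0.01, 0.1)
  z <- rnorm(8, 0.3, 0.2)
  d <- data.frame(z = z, v = v)
  expect_equal(re_meta(z ~ 1, vi = v, data = d)$b,
               c(`(Intercept)` = dl_naive(z, v)$pooled))
})

test_that("noiseless moderator slope is recovered exactly", {
  x <- seq(-1, 1, length.out = 8)
  d <- data.frame(z = 0.5 * x, x = x, v = rep(0.01, 8))
  f <- re_meta(z ~ x, vi = v, data = d)
  expect_equal(unname(f$b[2]), 0.5, tolerance = 1e-10)
  expect_equal(f$tau2, 0)
  pr <- predict(f, data.frame(x = c(-1, 1)))
  expect_equal(pr$r, tanh(c(-0.5, 0.5)), tolerance = 1e-10)
})

test_that("rank-deficient moderator designs name the collinear columns", {
  set.seed(14)
  d <- data.frame(z = rnorm(8, 0.3, 0.2), v = rep(0.02, 8), a = rnorm(8))
  d$b <- 2 * d$a
  expect_error(re_meta(z ~ a + b, vi = v, data = d), "collinear.*b")
  expect_error(
    re_meta(z ~ a, vi = v, data = d[1:2, ]),
    "more effect sizes")
})

test_that("null moderator slope p-values are calibrated near nominal", {
  ni <- c(21, 33, 28, 40, 17, 44, 45, 40)
  vi <- 1 / (ni - 3)
  set.seed(103)
  x <- rnorm(8)
  ps <- replicate(2000, {
    z <- rnorm(8, 0.33, sqrt(vi))
    re_meta(z ~ x, vi = vi, data = data.frame(z = z, x = x))$pval[2]
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.02)
  expect_lt(abs(mean(ps < 0.10) - 0.10), 0.03)
  # approximately uniform: small KS distance (the normal-reference Wald p
  # with estimated tau2 is not exactly uniform at k = 8)
  D <- max(abs(sort(ps) - ppoints(length(ps), a = 0)))
  expect_lt(D, 0.05)
})

test_that("compare_pooled matches direct arithmetic and symmetry", {
  ct <- compare_pooled(0.1, 103, 0.3, 103)
  byhand <- (atanh(0.3) - atanh(0.1)) / sqrt(2 / 100)
  expect_equal(unname(ct$statistic), byhand, tolerance = 1e-12)
  same <- compare_pooled(0.25, 50, 0.25, 80)
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p.value, 1)
  expect_error(compare_pooled(0.1, 3, 0.3, 100), "exceed 3")
})

test_that("p_from_estimate_ci inverts a symmetric-Z interval exactly", {
  se <- 0.07
  z0 <- 0.25
  ci <- tanh(c(z0 - 1.96 * se, z0 + 1.96 * se))
  # recovered SE reproduces the one used to build the interval
  se_back <- (atanh(ci[2]) - atanh(ci[1])) / (2 * qnorm(0.975))
  expect_equal(se_back, se * 1.96 / qnorm(0.975), tolerance = 1e-12)
  p <- p_from_estimate_ci(tanh(z0), ci[1], ci[2])
  expect_equal(p, 2 * pnorm(z0 / se_back, lower.tail = FALSE),
               tolerance = 1e-12)
  ci0 <- tanh(c(-1.96, 1.96) * se)
  expect_equal(p_from_estimate_ci(0, ci0[1], ci0[2]), 1)
  expect_error(p_from_estimate_ci(0.5, 0.6, 0.9), "bracket")
})

test_that("pool_by_pair fits one model per trait pair", {
  cfg <- demo_truth_config(n_per_year = 60, seed = 15)
  es <- year_effect_sizes(simulate_assays(cfg))
  fits <- pool_by_pair(es)
  expect_named(fits, unique(es$pair))
  expect_true(all(vapply(fits, function(f) f$k, numeric(1)) == 5))
})
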