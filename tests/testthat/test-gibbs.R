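test_that("psrf matches the between/within-chain formula", {
  set.seed(21)
  c1 <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  c2 <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  # identical chains converge to exactly sqrt((n-1)/n)
  r_same <- psrf(list(c1, c1))
  expect_equal(unname(r_same), rep(sqrt(99 / 100), 2), tolerance = 1e-12)
  # chains from far-apart distributions blow up
  r_far <- psrf(list(c1, c2 + 5))
  expect_true(all(r_far > 1.1))
  # direct textbook formula on fixed arrays
  x <- cbind(c1[, 1], c2[, 1])
  W <- mean(apply(x, 2, var))
  B <- nrow(x) * var(colMeans(x))
  byhand <- sqrt(((nrow(x) - 1) / nrow(x) * W + B / nrow(x)) / W)
  expect_equal(unname(psrf(list(c1, c2))[1]), byhand, tolerance = 1e-12)
})

test_that("models without replicated individuals are unidentified", {
  cfg <- tc_single(n = 30, reps = c("1" = 1), seed = 22)
  tab <- simulate_assays(cfg)
  expect_error(vc_mcmc(tab, "fid_m", control = ctl_fast()),
               "unidentified")
  expect_error(within_year_fits(tab, "fid_m", years = "2011",
                                control = ctl_fast()),
               "unidentified")
})

test_that("univariate sampler recovers repeatability, slope and null", {
  # R = 0.5 with a known date effect
  cfg <- tc_single(n = 150, reps = c("4" = 1), R = 0.5, v_tot = 1,
                   date_slopes = c(2, 0, 0), seed = 23)
  tab <- simulate_assays(cfg)
  fit <- vc_mcmc(tab, "novelty_avoidance_s", control = ctl_fast(seed = 23))
  s <- fit$summary
  g <- function(p) s$mean[s$parameter == p]
  expect_lt(abs(g("R") - 0.5), 0.12)
  expect_lt(abs(g("date") - 2), 0.2)
  # ANOVA ICC oracle on the same data after removing the date effect
  tab$adj <- tab$novelty_avoidance_s - 2 * tab$assay_date
  ms <- summary(stats::aov(adj ~ individual_id, data = tab))[[1]]$`Mean Sq`
  icc <- (ms[1] - ms[2]) / (ms[1] + 3 * ms[2])
  expect_lt(abs(g("R") - icc), 0.06)
  # all repeatability draws live in [0, 1]
  draws <- do.call(rbind, fit$draws)
  expect_true(all(draws$R >= 0 & draws$R <= 1))
  expect_true(all(draws$V_ind > 0 & draws$V_e > 0))

  # R = 0: posterior mean stays near zero (prior mass near 0)
  cfg0 <- tc_single(n = 150, reps = c("4" = 1), R = 0, v_tot = 1, seed = 24)
  fit0 <- vc_mcmc(simulate_assays(cfg0), "novelty_avoidance_s",
                  control = ctl_fast(seed = 24))
  expect_lt(fit0$summary$mean[fit0$summary$parameter == "R"], 0.08)
})

test_that("repeatability is invariant to affine rescaling of the response", {
  cfg <- tc_single(n = 100, reps = c("3" = 1), R = 0.4, v_tot = 1, seed = 25)
  tab <- simulate_assays(cfg)
  tab2 <- tab
  tab2$novelty_avoidance_s <- 7.3 * tab$novelty_avoidance_s - 120
  f1 <- vc_mcmc(tab, "novelty_avoidance_s", control = ctl_fast(seed = 7))
  f2 <- vc_mcmc(tab2, "novelty_avoidance_s", control = ctl_fast(seed = 7))
  g <- function(f) f$summary$mean[f$summary$parameter == "R"]
  expect_lt(abs(g(f1) - g(f2)), 0.02)
})

test_that("bivariate sampler recovers correlation components", {
  cfg <- tc_single(n = 150, reps = c("4" = 1), R = 0.5, v_tot = 1,
                   r_ind = c(0.6, 0, 0), r_e = c(0.1, 0, 0), seed = 26)
  tab <- simulate_assays(cfg)
  fit <- vc_mcmc(tab, c("novelty_avoidance_s", "aggression_latency_s"),
                 control = ctl_fast(seed = 26))
  s <- fit$summary
  g <- function(p) s$mean[s$parameter == p]
  expect_lt(abs(g("r_ind") - 0.6), 0.17)
  expect_lt(abs(g("r_e") - 0.1), 0.17)
  expect_lt(abs(g("R_1") - 0.5), 0.12)
  expect_lt(abs(g("R_2") - 0.5), 0.12)
  draws <- do.call(rbind, fit$draws)
  expect_true(all(abs(draws$r_ind) <= 1 & abs(draws$r_e) <= 1))
  # per-draw 2x2 matrices are positive definite
  det_ind <- draws$V_ind_11 * draws$V_ind_22 - draws$V_ind_12^2
  expect_true(all(det_ind > 0))

  # with no individual signal the between-individual correlation is weakly
  # identified: wide posterior spread
  cfg0 <- tc_single(n = 80, reps = c("3" = 1), R = 0, v_tot = 1, seed = 27)
  fit0 <- vc_mcmc(simulate_assays(cfg0),
                  c("novelty_avoidance_s", "aggression_latency_s"),
                  control = ctl_fast(seed = 27))
  ri <- fit0$summary[fit0$summary$parameter == "r_ind", ]
  expect_gt(ri$hi95 - ri$lo95, 0.5)
})

test_that("within-year and between-year fits use the right subsets", {
  tab <- cross_year_table(n_id = 80, n_years = 3, reps = 2,
                          R_btw = 0.1, R_wth = 0.45, seed = 28)
  wf <- within_year_fits(tab, "novelty_avoidance_s",
                         control = ctl_fast(seed = 28))
  expect_named(wf, c("2001", "2002", "2003"))
  expect_true(all(vapply(wf, function(f) f$n_observations, numeric(1)) ==
                    160))
  bf <- between_year_fit(tab, "novelty_avoidance_s",
                         control = ctl_fast(seed = 28))
  # between-year fit: first assay per year only, all birds in >= 2 years
  expect_equal(bf$n_individuals, 80)
  expect_equal(bf$n_observations, 240)
  R_w <- mean(vapply(wf, function(f)
    f$summary$mean[f$summary$parameter == "R"], numeric(1)))
  R_b <- bf$summary$mean[bf$summary$parameter == "R"]
  expect_lt(R_b, R_w)
  expect_lt(abs(R_b - 0.1), 0.15)
  tabr <- repeatability_table(wf, bf)
  expect_equal(tabr$context, c("2001", "2002", "2003", "between"))
  expect_true(all(tabr$R_lo <= tabr$R & tabr$R <= tabr$R_hi))
})

test_that("chains started from different seeds converge (PSRF < 1.1)", {
  cfg <- tc_single(n = 100, reps = c("3" = 1), R = 0.4, v_tot = 1, seed = 29)
  fit <- vc_mcmc(simulate_assays(cfg), "fid_m",
                 control = mcmc_control(iterations = 8000, burn_in = 2000,
                                        thin = 5, chains = 3, seed = 29))
  expect_true(all(fit$psrf < 1.1))
})
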