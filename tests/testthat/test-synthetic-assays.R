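test_that("truth_config rejects invalid covariance and repeat inputs", {
  bad <- diag(3); bad[1, 2] <- bad[2, 1] <- 2  # not PSD
  expect_error(
    truth_config(years = "2011", n_individuals = 10, sigma_ind = bad,
                 sigma_e = diag(3)),
    "sigma_ind.*positive semi-definite")
  expect_error(
    truth_config(years = "2011", n_individuals = 10, sigma_ind = diag(3),
                 sigma_e = bad),
    "sigma_e.*positive semi-definite")
  expect_error(
    truth_config(years = "2011", n_individuals = 10, sigma_ind = diag(3),
                 sigma_e = diag(3), repeats_distribution = c("7" = 1)),
    "support")
  expect_error(
    truth_config(years = "2011", n_individuals = 10, sigma_ind = diag(3),
                 sigma_e = diag(3), censor_threshold = -1),
    "censor_threshold")
})

test_that("zero individual variance leaves only residual spread in means", {
  cfg <- tc_single(n = 400, reps = c("4" = 1), R = 0, v_tot = 1, seed = 3)
  tab <- simulate_assays(cfg)
  ids <- tab$individual_id
  m_i <- tapply(tab$novelty_avoidance_s, ids, mean)
  n_i <- tapply(tab$novelty_avoidance_s, ids, length)
  # per-individual means vary only through residual/replicates
  expect_lt(abs(var(m_i) - mean(1 / n_i)), 0.05)
})

test_that("perfect between-individual correlation with no residual noise", {
  cfg <- tc_single(n = 60, reps = c("2" = 1), R = 1, v_tot = 1,
                   r_ind = c(1, 0, 0), seed = 4)
  tab <- simulate_assays(cfg)
  m1 <- tapply(tab$novelty_avoidance_s, tab$individual_id, mean)
  m2 <- tapply(tab$aggression_latency_s, tab$individual_id, mean)
  expect_equal(unname(cor(m1, m2, method = "spearman")), 1)
})

test_that("simulated repeatability matches the one-way ANOVA ICC oracle", {
  cfg <- tc_single(n = 500, reps = c("4" = 1), R = 0.5, v_tot = 1, seed = 5)
  tab <- simulate_assays(cfg)
  # closed-form ICC from one-way ANOVA mean squares
  fit <- stats::aov(novelty_avoidance_s ~ individual_id, data = tab)
  ms <- summary(fit)[[1]]$`Mean Sq`
  k <- 4
  icc <- (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
  expect_lt(abs(icc - 0.5), 0.07)
})

test_that("capture model extremes behave as documented", {
  cfg <- tc_single(n = 80, reps = c("1" = 0.5, "3" = 0.5),
                   capture_intercept = Inf, seed = 6)
  tab <- simulate_assays(cfg)
  expect_true(all(tab$captured))
  expect_true(all(!is.na(tab$individual_id)))

  none <- apply_capture_bias(tab, list(intercept = -Inf,
                                       slopes = c(0, 0, 0)), seed = 1)
  expect_true(all(!none$captured))
  expect_true(all(is.na(none$individual_id)))
  expect_true(all(none$assay_order == 1L))
})

test_that("negative boldness slope leaves the captured subsample bolder", {
  # smaller value = bolder; negative slopes on the scores mean shy (large)
  # birds are harder to capture, so captured birds have smaller mean scores
  cfg <- tc_single(n = 1000, reps = c("1" = 1), R = 0.3, v_tot = 1,
                   capture_intercept = 0.5,
                   capture_slopes = c(-1, -1, -1), seed = 7)
  tab <- simulate_assays(cfg)
  first <- first_assays(tab)
  cap <- first$captured
  expect_gt(mean(cap), 0.2)
  expect_lt(mean(cap), 0.9)
  tt <- t.test(first$novelty_avoidance_s[cap],
               first$novelty_avoidance_s, alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("assay CSV round-trips losslessly including missing identities", {
  cfg <- tc_single(n = 40, reps = c("1" = 0.4, "2" = 0.6),
                   capture_intercept = 0.4, seed = 8)
  tab <- simulate_assays(cfg)
  expect_gt(sum(is.na(tab$individual_id)), 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(tab, f)
  back <- read_assay_csv(f)
  attr(tab, "truth") <- NULL
  expect_equal(back, tab, tolerance = 1e-12)

  # header-only round trip
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(tab[0, ], f2)
  expect_equal(nrow(read_assay_csv(f2)), 0L)

  # unknown column is a schema error
  raw <- utils::read.csv(f)
  raw$extra <- 1
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, f3, row.names = FALSE)
  expect_error(read_assay_csv(f3), "unknown column.*extra")

  # malformed numeric reported with its line number
  lines <- readLines(f)
  parts <- strsplit(lines[3], ",")[[1]]
  parts[5] <- "oops"
  lines[3] <- paste(parts, collapse = ",")
  f4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines, f4)
  expect_error(read_assay_csv(f4), "line\\(s\\) 3")
})

test_that("identical config and seed give byte-identical CSVs", {
  cfg <- default_truth_config(seed = 42)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_assay_csv(simulate_assays(cfg), f1)
  write_assay_csv(simulate_assays(default_truth_config(seed = 42)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("adding a year does not perturb earlier years' draws", {
  cfg5 <- demo_truth_config(n_per_year = 40, seed = 9)
  tab5 <- simulate_assays(cfg5)
  cfg4 <- cfg5
  keep <- cfg5$years[1:4]
  cfg4$years <- keep
  cfg4$n_individuals <- cfg5$n_individuals[keep]
  cfg4$sigma_ind <- cfg5$sigma_ind[keep]
  cfg4$sigma_e <- cfg5$sigma_e[keep]
  cfg4$repeats_distribution <- cfg5$repeats_distribution[keep]
  cfg4$prop_juvenile <- cfg5$prop_juvenile[keep]
  tab4 <- simulate_assays(cfg4)
  expect_equal(tab5[tab5$year %in% keep, ], tab4, ignore_attr = TRUE)
})

test_that("censoring respects the ceiling and grows with the latency mean", {
  fracs <- vapply(c(150, 220, 290), function(mu_ag) {
    cfg <- tc_single(n = 300, mu = c(0, mu_ag, 50), v_tot = 10000,
                     R = 0.4, censor_threshold = 301, seed = 10)
    tab <- simulate_assays(cfg)
    expect_true(all(tab$aggression_latency_s <= 301))
    expect_true(all(tab$censored_aggression ==
                      (tab$aggression_latency_s == 301)))
    mean(tab$censored_aggression)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})
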