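test_that("competition index arithmetic and degenerate windows", {
  # all efforts within a 10-day window that contains 100% >= 90%
  idx <- competition_index(60, 100, c(1, 3, 5, 7, 10))
  expect_equal(as.numeric(idx), 0.06)
  expect_equal(attr(idx, "interval_days"), 10)
  same_day <- competition_index(30, 60, rep(12, 8))
  expect_equal(attr(same_day, "interval_days"), 1)
  expect_equal(as.numeric(same_day), 0.5)
  expect_error(competition_index(10, 0, 1:3), "positive")
  expect_error(competition_index(10, 50, integer(0)), "at least one")
})

test_that("shortest 90% window matches an exhaustive scan", {
  brute <- function(d, cov) {
    n <- length(d)
    m <- ceiling(cov * n)
    best <- Inf
    for (lo in sort(unique(d))) for (hi in sort(unique(d))) {
      if (hi < lo) next
      if (sum(d >= lo & d <= hi) >= m) best <- min(best, hi - lo + 1)
    }
    max(1, best)
  }
  set.seed(51)
  for (i in 1:20) {
    d <- sample.int(20, 100, replace = TRUE)
    expect_equal(shortest_window(d, 0.9), brute(d, 0.9))
    expect_equal(shortest_window(d, 0.5), brute(d, 0.5))
  }
  # window length is monotone non-increasing as coverage decreases
  d <- sample.int(30, 200, replace = TRUE)
  lens <- vapply(c(1, 0.9, 0.7, 0.5, 0.3), shortest_window, numeric(1),
                 dates = d)
  expect_true(all(diff(lens) <= 0))
})

test_that("competition index is scale invariant in efforts and boxes", {
  d <- c(2, 5, 9, 14, 20)
  a <- competition_index(40, 80, d)
  b <- competition_index(40 * 5, 80 * 5, d)
  expect_equal(as.numeric(a), as.numeric(b))
})

test_that("age structure and sqrt transform validate their domains", {
  expect_equal(age_structure(0, 40), 0)
  expect_equal(age_structure(40, 40), 1)
  expect_equal(age_structure(13, 40), 0.325)
  expect_error(age_structure(5, 0), "positive")
  expect_error(age_structure(41, 40), "n_total")
  expect_equal(sqrt_transform(0), 0)
  expect_equal(sqrt_transform(0.25), 0.5)
  expect_error(sqrt_transform(-0.1), "negative")
})

test_that("predation is lagged one year, order independent", {
  expect_warning(out <- lag_predation(c(2009, 2010), c(0.2, 0.4)), "2009")
  expect_equal(out, c("2010" = 0.2))
  expect_warning(single <- lag_predation(2009, 0.2), "no year")
  expect_length(single, 0)
  yrs <- c(2007, 2009, 2010, 2011)
  r <- c(0.1, 0.2, 0.3, 0.4)
  set.seed(52)
  o <- sample(4)
  expect_warning(a <- lag_predation(yrs, r), "2007")
  expect_warning(b <- lag_predation(yrs[o], r[o]), "2007")
  expect_equal(a[sort(names(a))], b[sort(names(b))])
})

test_that("collinearity screen flags at the configured threshold", {
  X <- data.frame(a = 1:9, b = 1:9, c = c(3, 1, 4, 1, 5, 9, 2, 6, 5))
  rep1 <- collinearity_screen(X)
  expect_true(rep1$flagged[rep1$var1 == "a" & rep1$var2 == "b"])
  expect_equal(rep1$r[rep1$var1 == "a" & rep1$var2 == "b"], 1)
  # a pair with r = -0.887 exactly is flagged at 0.8 but not at 0.9
  set.seed(53)
  x <- rnorm(9)
  e <- residuals(lm(rnorm(9) ~ x))
  xs <- scale(x)[, 1]
  y <- -0.887 * xs / sd(xs) - sqrt(1 - 0.887^2) * e / sd(e)
  expect_equal(cor(x, y), -0.887, tolerance = 1e-12)
  rep2 <- collinearity_screen(data.frame(x = x, y = y, z = rnorm(9)))
  row <- rep2[rep2$var1 == "x" & rep2$var2 == "y", ]
  expect_true(row$flagged)
  rep3 <- collinearity_screen(data.frame(x = x, y = y), threshold = 0.9)
  expect_false(rep3$flagged[1])
})

test_that("moderator_table assembles and transforms the four covariates", {
  raw <- data.frame(
    year = 2009:2012,
    mean_temp_c = c(9.1, 10.4, 8.7, 11.2),
    predation_rate = c(0.10, 0.25, 0.00, 0.49),
    breeding_efforts = c(40, 60, 30, 55),
    available_boxes = c(100, 100, 120, 110),
    interval_days = c(10, 12, 8, 15),
    n_juvenile = c(10, 20, 6, 22),
    n_total = c(40, 50, 30, 44))
  mt <- moderator_table(raw)
  expect_s3_class(mt, "moderator_table")
  expect_equal(mt$predation_prev, c(NA, 0.10, 0.25, 0.00))
  expect_equal(mt$competition, (raw$breeding_efforts /
                                  raw$available_boxes) / raw$interval_days)
  expect_equal(mt$prop_juvenile, c(0.25, 0.4, 0.2, 0.5))
  expect_equal(mt$prop_juvenile_sqrt, sqrt(mt$prop_juvenile))
  expect_equal(mt$predation_prev_sqrt[-1], sqrt(mt$predation_prev[-1]))
  # round trip through CSV
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(raw, f, row.names = FALSE)
  expect_equal(read_moderator_csv(f), mt)
  expect_error(moderator_table(raw[, -2]), "missing column")
})
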