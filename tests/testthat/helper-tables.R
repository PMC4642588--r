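# Shared fixture builders. Everything is generated in code; no files.

# single-year truth with equal-diagonal components: per-trait repeatability
# R, total variance v_tot, optional pairwise correlations for (NA-AG, NA-RT,
# AG-RT). Means sit far from the censoring/positivity clamps unless a low
# ceiling is requested explicitly.
tc_single <- function(n = 100, reps = c("4" = 1), R = 0.5, v_tot = 1,
                      r_ind = c(0, 0, 0), r_e = c(0, 0, 0),
                      mu = c(0, 100, 50), date_slopes = c(0, 0, 0),
                      censor_threshold = 1e4, capture_intercept = Inf,
                      capture_slopes = c(0, 0, 0), seed = 1L) {
  cov3 <- function(vars, cors) {
    s <- sqrt(vars); m <- diag(vars)
    m[1, 2] <- m[2, 1] <- cors[1] * s[1] * s[2]
    m[1, 3] <- m[3, 1] <- cors[2] * s[1] * s[3]
    m[2, 3] <- m[3, 2] <- cors[3] * s[2] * s[3]
    m
  }
  truth_config(
    years = "2011", n_individuals = n, mu = mu,
    sigma_ind = cov3(rep(v_tot * R, 3), r_ind),
    sigma_e = cov3(rep(v_tot * (1 - R), 3), r_e),
    date_slopes = date_slopes,
    repeats_distribution = reps,
    censor_threshold = censor_threshold,
    capture_model = list(intercept = capture_intercept,
                         slopes = capture_slopes),
    seed = seed)
}

# hand-built assay table with individuals repeated across years (the
# generator does not model survival between years): n_id birds, each seen
# in n_years years, within-year repeats 'reps'. Individual effects give
# between-year repeatability R_btw of trait 1; within a year an extra
# year-by-individual effect raises the within-year repeatability.
cross_year_table <- function(n_id = 60, n_years = 3, reps = 2,
                             R_btw = 0.1, R_wth = 0.4, seed = 1) {
  set.seed(seed)
  v_id <- R_btw
  v_yr <- R_wth - R_btw          # year-by-individual component
  v_e <- 1 - R_wth
  rows <- list()
  for (i in seq_len(n_id)) {
    b <- rnorm(1, 0, sqrt(v_id))
    for (y in seq_len(n_years)) {
      u <- rnorm(1, 0, sqrt(max(v_yr, 0)))
      for (k in seq_len(reps)) {
        rows[[length(rows) + 1L]] <- data.frame(
          year = as.character(2000 + y),
          individual_id = sprintf("id%03d", i),
          assay_order = k, assay_date = sample.int(40L, 1L),
          novelty_avoidance_s = b + u + rnorm(1, 0, sqrt(v_e)),
          aggression_latency_s = 100, fid_m = 50,
          captured = TRUE, age_class = "adult",
          censored_aggression = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

# quick MCMC settings for tests that only need posterior means
ctl_fast <- function(seed = 1L, chains = 2L)
  mcmc_control(iterations = 6000L, burn_in = 1000L, thin = 5L,
               chains = chains, seed = seed)

# naive two-pass textbook DerSimonian-Laird pool, used as the independent
# oracle for re_meta(z ~ 1)
dl_naive <- function(z, v) {
  w <- 1 / v
  zbar <- sum(w * z) / sum(w)
  Q <- sum(w * (z - zbar)^2)
  df <- length(z) - 1
  tau2 <- max(0, (Q - df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  pooled <- sum(ws * z) / sum(ws)
  list(pooled = pooled, se = sqrt(1 / sum(ws)), tau2 = tau2, Q = Q)
}
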