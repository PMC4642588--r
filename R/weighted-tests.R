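#' Weighted mean and variance of per-year statistics
#'
#' Frequency-weighted mean `sum(w * v) / sum(w)` and the bias-corrected
#' weighted variance `[sum(w * (v - mean)^2) / sum(w)] * n / (n - 1)` where
#' `n` is the number of years (values), not the total weight. This is the
#' normalization under which per-year estimates weighted by their sample
#' sizes behave like `n` observations in a t test with `n - 1` degrees of
#' freedom.
#'
#' @param values per-year statistics (e.g. repeatabilities).
#' @param weights positive per-year weights (e.g. numbers of individuals).
#' @return list with `mean`, `variance`, `n`.
#' @export
weighted_mean_var <- function(values, weights) {
  if (length(values) != length(weights)) stop("values and weights must match")
  if (any(weights <= 0)) stop("weights must be positive")
  ok <- stats::complete.cases(values, weights)
  values <- values[ok]; weights <- weights[ok]
  n <- length(values)
  if (n < 1L) stop("no complete value/weight pairs")
  m <- sum(weights * values) / sum(weights)
  v <- if (n > 1L)
    sum(weights * (values - m)^2) / sum(weights) * n / (n - 1) else NA_real_
  list(mean = m, variance = v, n = n)
}

#' Sample-size-weighted one-sample t test
#'
#' Tests whether per-year statistics differ systematically from a reference
#' value `mu0` (e.g. whether within-year repeatabilities exceed the
#' between-year repeatability), using the weighted mean and variance of
#' [weighted_mean_var()]: `t = (mean - mu0) / sqrt(variance / n)` on
#' `n - 1` degrees of freedom, two-sided.
#'
#' @param values per-year statistics.
#' @param weights per-year sample sizes.
#' @param mu0 reference value.
#' @return object of class `"htest"`.
#' @export
weighted_t_one_sample <- function(values, weights, mu0 = 0) {
  wv <- weighted_mean_var(values, weights)
  if (wv$n < 2L) stop("need at least two years")
  se <- sqrt(wv$variance / wv$n)
  t <- if (se == 0) {
    if (wv$mean == mu0) 0 else sign(wv$mean - mu0) * Inf
  } else (wv$mean - mu0) / se
  df <- wv$n - 1L
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  structure(list(statistic = c(t = t), parameter = c(df = df), p.value = p,
                 estimate = c(`weighted mean` = wv$mean), null.value =
                   c(mean = mu0), stderr = se, alternative = "two.sided",
                 method = "Weighted one-sample t test (weights = sample sizes)",
                 data.name = deparse(substitute(values))),
            class = "htest")
}

#' Sample-size-weighted paired t test
#'
#' Compares two sets of per-year statistics (e.g. within-year
#' repeatabilities of two traits) by applying the weighted one-sample t test
#' to their per-year differences `a - b`. When the two traits have unequal
#' per-year sample sizes, the conventional weight is their pairwise minimum.
#'
#' @param a,b paired per-year statistics.
#' @param weights per-year weights (e.g. `pmin(n_a, n_b)`).
#' @return object of class `"htest"`.
#' @export
weighted_t_paired <- function(a, b, weights) {
  if (length(a) != length(b)) stop("a and b must be paired")
  out <- weighted_t_one_sample(a - b, weights, mu0 = 0)
  out$method <- "Weighted paired t test (weights = sample sizes)"
  out$data.name <- paste(deparse(substitute(a)), "vs",
                         deparse(substitute(b)))
  out
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values into `chi2 = -2 * sum(log(p))`, referred
#' to a chi-square distribution with `2k` degrees of freedom.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return object of class `"htest"` with the chi-square statistic, df and
#'   combined p-value.
#' @export
fisher_combined <- function(p_values) {
  if (!length(p_values)) stop("no p-values supplied")
  if (any(is.na(p_values)) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  structure(list(statistic = c(`X-squared` = chi2), parameter = c(df = df),
                 p.value = p, alternative = "less (combined evidence)",
                 method = "Fisher's combined probability test",
                 data.name = deparse(substitute(p_values))),
            class = "htest")
}

#' Weighted repeatability comparisons across contexts
#'
#' Convenience wrapper running the study's inference layer on a
#' repeatability table in the layout of [fly_repeatability]: for each trait,
#' a weighted one-sample t test of the within-year repeatabilities against
#' the between-year value, the three pairwise weighted paired t tests
#' between traits (pairwise-minimum weights), and Fisher's combined
#' probability over the three one-sample tests.
#'
#' @param rep_table data frame in the layout of [fly_repeatability]
#'   (default: that table itself).
#' @return list with `one_sample` (named list of `"htest"`),
#'   `paired` (named list of `"htest"`), and `combined` (`"htest"`).
#' @export
repeatability_tests <- function(rep_table = fly_repeatability) {
  within <- rep_table[rep_table$context != "between", ]
  between <- rep_table[rep_table$context == "between", ]
  traits <- c(na = "na", ag = "ag", rt = "rt")
  one_sample <- lapply(traits, function(tr) {
    weighted_t_one_sample(within[[paste0("R_", tr)]],
                          within[[paste0("n_", tr)]],
                          mu0 = between[[paste0("R_", tr)]])
  })
  pair_of <- list(na_ag = c("na", "ag"), na_rt = c("na", "rt"),
                  ag_rt = c("ag", "rt"))
  paired <- lapply(pair_of, function(tp) {
    weighted_t_paired(within[[paste0("R_", tp[1])]],
                      within[[paste0("R_", tp[2])]],
                      pmin(within[[paste0("n_", tp[1])]],
                           within[[paste0("n_", tp[2])]]))
  })
  combined <- fisher_combined(vapply(one_sample, `[[`, numeric(1),
                                     "p.value"))
  list(one_sample = one_sample, paired = paired, combined = combined)
}
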