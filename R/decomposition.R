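#' Expected phenotypic correlation from its components
#'
#' The phenotypic correlation between two traits measured once per
#' individual mixes the correlation of individual-specific mean levels
#' (`r_ind`) and the correlation of within-individual deviations (`r_e`),
#' weighted by the traits' repeatabilities:
#'
#' `r_P = r_ind * sqrt(R_x * R_y) + r_e * sqrt((1 - R_x) * (1 - R_y))`
#'
#' At `R_x = R_y = 1` the phenotypic correlation equals the
#' between-individual correlation; at `R_x = R_y = 0` it equals the
#' within-individual correlation.
#'
#' @param R_x,R_y repeatabilities in \[0, 1\].
#' @param r_ind between-individual correlation in \[-1, 1\].
#' @param r_e within-individual correlation in \[-1, 1\].
#' @return the expected phenotypic correlation (vectorized).
#' @export
expected_phenotypic_r <- function(R_x, R_y, r_ind, r_e) {
  if (any(R_x < 0 | R_x > 1 | R_y < 0 | R_y > 1))
    stop("repeatabilities must lie in [0, 1]")
  if (any(abs(r_ind) > 1 | abs(r_e) > 1))
    stop("correlations must lie in [-1, 1]")
  r_ind * sqrt(R_x * R_y) + r_e * sqrt((1 - R_x) * (1 - R_y))
}

#' Expected phenotypic correlations implied by a ground truth
#'
#' Evaluates [expected_phenotypic_r()] on the true covariance components of
#' a [truth_config()], per year and trait pair.
#'
#' @param config a `"truth_config"`.
#' @return data frame with `year`, `pair`, `R_x`, `R_y`, `r_ind`, `r_e`,
#'   `r_P_expected`.
#' @export
truth_phenotypic_r <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  idx <- list("NA-AG" = c(1L, 2L), "NA-RT" = c(1L, 3L), "AG-RT" = c(2L, 3L))
  out <- list()
  for (y in config$years) {
    si <- config$sigma_ind[[y]]
    se <- config$sigma_e[[y]]
    for (p in names(idx)) {
      i <- idx[[p]][1]; j <- idx[[p]][2]
      Rx <- si[i, i] / (si[i, i] + se[i, i])
      Ry <- si[j, j] / (si[j, j] + se[j, j])
      ri <- if (si[i, i] > 0 && si[j, j] > 0)
        si[i, j] / sqrt(si[i, i] * si[j, j]) else 0
      re <- if (se[i, i] > 0 && se[j, j] > 0)
        se[i, j] / sqrt(se[i, i] * se[j, j]) else 0
      out[[length(out) + 1L]] <- data.frame(
        year = y, pair = p, R_x = Rx, R_y = Ry, r_ind = ri, r_e = re,
        r_P_expected = expected_phenotypic_r(Rx, Ry, ri, re),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Validate reconstructed phenotypic correlations against observed ones
#'
#' Pearson correlation between the component-based expected phenotypic
#' correlations and the phenotypic correlations actually observed (one
#' observation per bird, all birds including unidentified ones). A strong
#' positive relationship indicates that the estimated within- and
#' between-individual components are reliable despite being derived from
#' the captured subsample only.
#'
#' @param expected numeric vector of expected phenotypic correlations.
#' @param observed numeric vector of observed phenotypic correlations
#'   (paired with `expected`; length at least 4).
#' @return object of class `"htest"` (Pearson correlation test), with the
#'   correlation in `$estimate`.
#' @export
reconstruction_validation <- function(expected, observed) {
  if (length(expected) != length(observed))
    stop("expected and observed must be paired")
  ok <- stats::complete.cases(expected, observed)
  if (sum(ok) < 4L) stop("need at least 4 paired values")
  stats::cor.test(expected[ok], observed[ok], method = "pearson")
}

#' Decompose year-by-pair correlations via bivariate mixed models
#'
#' For each year with replicated individuals and each trait pair, fits the
#' bivariate variance partition ([vc_mcmc()]), extracts posterior-mean
#' repeatabilities and within-/between-individual correlations, combines
#' them into the expected phenotypic correlation, and pairs the result with
#' the phenotypic correlation observed on first assays of the full sample.
#'
#' @param table assay table.
#' @param years years to decompose (default: all years where the bivariate
#'   model is identified).
#' @param pairs trait pairs (default all three).
#' @param control an [mcmc_control()].
#' @param min_n minimum pairwise-complete first-assay sample for the
#'   observed correlation.
#' @return data frame with `year`, `pair`, `R_x`, `R_y`, `r_ind`, `r_e`,
#'   `r_P_expected`, `r_P_observed`, `max_psrf`.
#' @export
decompose_pairs <- function(table, years = NULL, pairs = .trait_pairs,
                            control = mcmc_control(), min_n = 5L) {
  .check_assay_table(table)
  pairs <- match.arg(pairs, .trait_pairs, several.ok = TRUE)
  if (is.null(years)) {
    has_reps <- vapply(split(table, table$year), function(s) {
      r <- table(s$individual_id[!is.na(s$individual_id)])
      sum(r >= 2L) >= 2L
    }, logical(1))
    years <- names(has_reps)[has_reps]
  }
  first <- first_assays(table)
  out <- list()
  for (y in years) {
    sub <- table[table$year == y, , drop = FALSE]
    fsub <- first[first$year == y, , drop = FALSE]
    for (p in pairs) {
      cols <- .pair_columns(p)
      fit <- vc_mcmc(sub, cols, control = control)
      s <- fit$summary
      g <- function(par) s$mean[s$parameter == par]
      r_obs <- tryCatch(spearman_rho(fsub[[cols[1]]], fsub[[cols[2]]]),
                        error = function(e) NA_real_)
      if (!is.na(r_obs) &&
          sum(!is.na(fsub[[cols[1]]]) & !is.na(fsub[[cols[2]]])) < min_n)
        r_obs <- NA_real_
      out[[length(out) + 1L]] <- data.frame(
        year = y, pair = p,
        R_x = g("R_1"), R_y = g("R_2"),
        r_ind = g("r_ind"), r_e = g("r_e"),
        r_P_expected = expected_phenotypic_r(
          min(max(g("R_1"), 0), 1), min(max(g("R_2"), 0), 1),
          g("r_ind"), g("r_e")),
        r_P_observed = r_obs,
        max_psrf = if (all(is.na(fit$psrf))) NA_real_ else
          max(fit$psrf, na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
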