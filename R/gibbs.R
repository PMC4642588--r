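#' MCMC control settings for the variance-partition models
#'
#' Desk-scale defaults: 3 chains of 20,000 iterations, burn-in 5,000,
#' thinning 10 — enough for random-intercept models of this size to converge
#' well below a PSRF of 1.1. Longer field-scale runs (millions of
#' iterations) are available by raising the settings.
#'
#' The variance prior is the weakly informative inverse-gamma form with
#' shape and scale 0.001 on univariate variance components; bivariate
#' covariance matrices use the matched inverse-Wishart with belief parameter
#' `nu = 1.002` and scale matrix `0.002 * I`, whose diagonal marginals
#' coincide with the univariate inverse-gamma. Fixed effects carry flat
#' (improper) priors.
#'
#' @param iterations total Gibbs iterations per chain.
#' @param burn_in iterations discarded from the start of each chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of independent chains (at least 2 for PSRF).
#' @param prior_shape,prior_scale inverse-gamma prior parameters for
#'   univariate variance components.
#' @param prior_nu inverse-Wishart belief parameter for 2x2 components.
#' @param seed integer seed; chain c uses substream `seed + c - 1`.
#' @return list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(iterations = 20000L, burn_in = 5000L, thin = 10L,
                         chains = 3L, prior_shape = 0.001,
                         prior_scale = 0.001, prior_nu = 1.002, seed = 1L) {
  stopifnot(burn_in < iterations, thin >= 1L, chains >= 1L,
            prior_shape > 0, prior_scale > 0)
  structure(list(iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 chains = as.integer(chains), prior_shape = prior_shape,
                 prior_scale = prior_scale, prior_nu = prior_nu,
                 seed = as.integer(seed)),
            class = "mcmc_control")
}

#' Bayesian variance partition of repeated behavioral measurements
#'
#' Fits a Gaussian random-intercept mixed model by a conjugate Gibbs
#' sampler. With one response trait the model is
#' `y_ij = b0 + b1 * date_ij + u_i + e_ij` with `u_i ~ N(0, V_ind)` and
#' `e_ij ~ N(0, V_e)`; the derived repeatability is
#' `R = V_ind / (V_ind + V_e)`. With two response traits the model is the
#' bivariate analogue with 2x2 between-individual and residual covariance
#' matrices, from which the between-individual correlation `r_ind` and the
#' within-individual correlation `r_e` are derived draw by draw.
#'
#' Rows without an individual identity are excluded (unidentified birds
#' cannot contribute repeats); the model requires at least two individuals
#' with at least two observations each, otherwise the variance components
#' are unidentified and an error is raised. Full conditionals: fixed effects
#' and random intercepts are normal; variances are inverse-gamma
#' (univariate) or inverse-Wishart (bivariate). Posterior summaries use the
#' pooled post-burn-in thinned draws of all chains; convergence is
#' summarized by the Gelman-Rubin potential scale reduction factor
#' (see [psrf()]).
#'
#' @param table assay table (see [simulate_assays()]).
#' @param response one or two trait column names (e.g.
#'   `"fid_m"` or `c("novelty_avoidance_s", "aggression_latency_s")`).
#' @param date_covariate include `assay_date` as fixed covariate
#'   (default `TRUE`, one slope per trait).
#' @param control an [mcmc_control()].
#' @return An object of class `"vc_fit"`: list with `draws` (one data frame
#'   of parameter draws per chain), `summary` (posterior mean, median and
#'   central 95% credible interval per parameter), `psrf`, `n_individuals`,
#'   `n_observations`, `response`, `bivariate`, `control`.
#' @seealso [repeatability()], [ind_cor()], [within_year_fits()],
#'   [between_year_fit()]
#' @export
vc_mcmc <- function(table, response, date_covariate = TRUE,
                    control = mcmc_control()) {
  .check_assay_table(table)
  stopifnot(length(response) %in% 1:2,
            all(response %in% names(table)))
  dat <- table[!is.na(table$individual_id), , drop = FALSE]
  keep <- stats::complete.cases(dat[, response, drop = FALSE])
  dat <- dat[keep, , drop = FALSE]
  reps <- table(dat$individual_id)
  if (sum(reps >= 2L) < 2L)
    stop("repeatability unidentified: need at least two individuals ",
         "with two or more observations")
  id <- match(dat$individual_id, names(reps))
  Y <- as.matrix(dat[, response, drop = FALSE])
  X <- if (date_covariate) cbind(1, date = dat$assay_date) else
    matrix(1, nrow(dat), 1)
  colnames(X) <- if (date_covariate) c("intercept", "date") else "intercept"

  chains <- lapply(seq_len(control$chains), function(ch) {
    set.seed(control$seed + ch - 1L)
    if (ncol(Y) == 1L)
      .gibbs_uni(drop(Y), X, id, length(reps), control)
    else
      .gibbs_bi(Y, X, id, length(reps), control, response)
  })
  draws_mat <- lapply(chains, as.matrix)
  pooled <- do.call(rbind, draws_mat)
  qs <- apply(pooled, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  summ <- data.frame(parameter = colnames(pooled),
                     mean = colMeans(pooled),
                     median = qs[2, ], lo95 = qs[1, ], hi95 = qs[3, ],
                     row.names = NULL)
  r_hat <- if (control$chains >= 2L) psrf(draws_mat) else
    stats::setNames(rep(NA_real_, ncol(pooled)), colnames(pooled))
  summ$psrf <- r_hat[summ$parameter]
  structure(list(draws = chains, summary = summ, psrf = r_hat,
                 n_individuals = length(reps), n_observations = nrow(dat),
                 response = response, bivariate = (ncol(Y) == 2L),
                 control = control),
            class = "vc_fit")
}

# univariate conjugate Gibbs sampler; returns data.frame of kept draws
.gibbs_uni <- function(y, X, id, q, ctl) {
  n <- length(y)
  p <- ncol(X)
  XtXi <- solve(crossprod(X))
  cXtXi <- chol(XtXi)
  n_i <- tabulate(id, q)
  a0 <- ctl$prior_shape; b0 <- ctl$prior_scale

  v_ind <- stats::var(y) / 2 + 1e-8
  v_e <- stats::var(y) / 2 + 1e-8
  u <- rep(0, q)
  beta <- rep(0, p)

  keep <- seq(ctl$burn_in + ctl$thin, ctl$iterations, by = ctl$thin)
  out <- matrix(NA_real_, length(keep), p + 3L)
  colnames(out) <- c(colnames(X), "V_ind", "V_e", "R")
  kk <- 0L
  for (it in seq_len(ctl$iterations)) {
    # fixed effects | rest
    resid_u <- y - u[id]
    bhat <- XtXi %*% crossprod(X, resid_u)
    beta <- drop(bhat + sqrt(v_e) * (t(cXtXi) %*% stats::rnorm(p)))
    # random intercepts | rest
    r <- y - drop(X %*% beta)
    prec <- n_i / v_e + 1 / v_ind
    mu_u <- (rowsum(r, id)[, 1] / v_e) / prec
    u <- mu_u + stats::rnorm(q) / sqrt(prec)
    # variances | rest
    v_ind <- 1 / stats::rgamma(1, a0 + q / 2, b0 + sum(u^2) / 2)
    e <- r - u[id]
    v_e <- 1 / stats::rgamma(1, a0 + n / 2, b0 + sum(e^2) / 2)
    if (it > ctl$burn_in && (it - ctl$burn_in) %% ctl$thin == 0L) {
      kk <- kk + 1L
      out[kk, ] <- c(beta, v_ind, v_e, v_ind / (v_ind + v_e))
    }
  }
  as.data.frame(out)
}

# bivariate sampler: 2x2 inverse-Wishart conditionals for both components
.gibbs_bi <- function(Y, X, id, q, ctl, response) {
  n <- nrow(Y)
  p <- ncol(X)
  XtXi <- solve(crossprod(X))
  cXtXi <- chol(XtXi)
  n_i <- tabulate(id, q)
  groups <- split(seq_len(q), n_i)
  nu0 <- ctl$prior_nu
  S0 <- diag(2) * 2 * ctl$prior_scale

  V_ind <- diag(apply(Y, 2, stats::var) / 2 + 1e-8)
  V_e <- V_ind
  U <- matrix(0, q, 2)
  B <- matrix(0, p, 2)

  keep <- seq(ctl$burn_in + ctl$thin, ctl$iterations, by = ctl$thin)
  nm <- c("intercept_1", if (p > 1) "date_1", "intercept_2",
          if (p > 1) "date_2",
          "V_ind_11", "V_ind_12", "V_ind_22",
          "V_e_11", "V_e_12", "V_e_22",
          "R_1", "R_2", "r_ind", "r_e")
  out <- matrix(NA_real_, length(keep), length(nm))
  colnames(out) <- nm
  kk <- 0L
  for (it in seq_len(ctl$iterations)) {
    # fixed effects | rest (matrix-normal draw)
    Ru <- Y - U[id, , drop = FALSE]
    Bhat <- XtXi %*% crossprod(X, Ru)
    B <- Bhat + t(cXtXi) %*% matrix(stats::rnorm(2 * p), p, 2) %*% chol(V_e)
    # random intercepts | rest, grouped by replicate count
    R <- Y - X %*% B
    S <- rowsum(R, id)                       # q x 2 sums of residuals
    Ve_inv <- solve(V_e)
    Vi_inv <- solve(V_ind)
    for (g in groups) {
      m <- n_i[g[1]]
      Sigma_u <- solve(m * Ve_inv + Vi_inv)
      L <- chol(Sigma_u)
      mu <- S[g, , drop = FALSE] %*% Ve_inv %*% Sigma_u
      U[g, ] <- mu + matrix(stats::rnorm(2 * length(g)), ncol = 2) %*% L
    }
    # covariance components | rest
    V_ind <- .riwish(nu0 + q, S0 + crossprod(U))
    E <- R - U[id, , drop = FALSE]
    V_e <- .riwish(nu0 + n, S0 + crossprod(E))
    if (it > ctl$burn_in && (it - ctl$burn_in) %% ctl$thin == 0L) {
      kk <- kk + 1L
      R1 <- V_ind[1, 1] / (V_ind[1, 1] + V_e[1, 1])
      R2 <- V_ind[2, 2] / (V_ind[2, 2] + V_e[2, 2])
      r_ind <- V_ind[1, 2] / sqrt(V_ind[1, 1] * V_ind[2, 2])
      r_e <- V_e[1, 2] / sqrt(V_e[1, 1] * V_e[2, 2])
      out[kk, ] <- c(B[, 1], B[, 2],
                     V_ind[1, 1], V_ind[1, 2], V_ind[2, 2],
                     V_e[1, 1], V_e[1, 2], V_e[2, 2],
                     R1, R2, r_ind, r_e)
    }
  }
  as.data.frame(out)
}

# inverse-Wishart draw via the Wishart of the inverse scale; fractional
# degrees of freedom handled through the Bartlett decomposition
.riwish <- function(nu, S) {
  p <- ncol(S)
  L <- chol(solve(S))                     # S^-1 = L'L
  A <- matrix(0, p, p)
  diag(A) <- sqrt(stats::rchisq(p, nu - seq_len(p) + 1))
  A[upper.tri(A)] <- stats::rnorm(p * (p - 1) / 2)
  W <- crossprod(A %*% L)                 # ~ Wishart(nu, S^-1)
  out <- solve(W)
  (out + t(out)) / 2
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes, per parameter, the classic between/within-chain variance ratio
#' `sqrt(((m-1)/m * W + B/m) / W)` where `W` is the mean within-chain
#' variance and `B` the between-chain variance of the chain means times the
#' chain length. Values near 1 indicate convergence; the conventional gate
#' is PSRF < 1.1.
#'
#' @param chains list of matrices or data frames (one per chain, equal
#'   dimensions; columns are parameters).
#' @return named numeric vector of PSRF values.
#' @export
psrf <- function(chains) {
  stopifnot(length(chains) >= 2L)
  mats <- lapply(chains, as.matrix)
  n <- nrow(mats[[1]])
  vapply(seq_len(ncol(mats[[1]])), function(j) {
    x <- vapply(mats, function(mm) mm[, j], numeric(n))
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W <= .Machine$double.eps) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1)) |> stats::setNames(colnames(mats[[1]]))
}

#' @export
print.vc_fit <- function(x, digits = 3, ...) {
  cat(if (x$bivariate) "Bivariate" else "Univariate",
      "variance partition:", paste(x$response, collapse = " / "), "\n")
  cat("  ", x$n_individuals, "individuals,", x$n_observations,
      "observations;", length(x$draws), "chains\n")
  show <- x$summary[grepl("^(R|r_ind|r_e)", x$summary$parameter), ]
  print(cbind(show["parameter"], round(show[, -1], digits)),
        row.names = FALSE)
  if (any(is.finite(x$psrf)) && max(x$psrf, na.rm = TRUE) >= 1.1)
    cat("  WARNING: max PSRF =", round(max(x$psrf, na.rm = TRUE), 3),
        ">= 1.1 — chains have not converged\n")
  invisible(x)
}

#' @export
summary.vc_fit <- function(object, ...) object$summary

#' @export
coef.vc_fit <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Trace plot of the variance-component draws
#'
#' @param x a `"vc_fit"`.
#' @param parameters parameters to show (default: repeatabilities and
#'   correlations).
#' @param ... passed to `matplot`.
#' @export
plot.vc_fit <- function(x, parameters = NULL, ...) {
  if (is.null(parameters))
    parameters <- grep("^(R|r_ind|r_e)", x$summary$parameter, value = TRUE)
  old <- graphics::par(mfrow = c(length(parameters), 1),
                       mar = c(2, 4, 1, 1))
  on.exit(graphics::par(old))
  for (p in parameters) {
    traces <- vapply(x$draws, function(d) d[[p]],
                     numeric(nrow(x$draws[[1]])))
    graphics::matplot(traces, type = "l", lty = 1, ylab = p, ...)
  }
  invisible(x)
}

#' Posterior summaries of derived quantities
#'
#' `repeatability()` returns the posterior mean and central 95% credible
#' interval of each trait's repeatability; `ind_cor()` returns those of the
#' between-individual (`r_ind`) and within-individual (`r_e`) correlations
#' of a bivariate fit.
#'
#' @param fit a `"vc_fit"`.
#' @return one-row-per-quantity data frame with `parameter`, `mean`,
#'   `median`, `lo95`, `hi95`, `psrf`.
#' @export
repeatability <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  fit$summary[grepl("^R(_[12])?$", fit$summary$parameter), , drop = FALSE]
}

#' @rdname repeatability
#' @export
ind_cor <- function(fit) {
  stopifnot(inherits(fit, "vc_fit"))
  if (!fit$bivariate) stop("correlations require a bivariate fit")
  fit$summary[fit$summary$parameter %in% c("r_ind", "r_e"), , drop = FALSE]
}

#' Per-year and between-year variance partitions
#'
#' `within_year_fits()` fits the model separately to each requested year
#' (using all assays of identified birds within that year).
#' `between_year_fit()` estimates the between-year repeatability: it keeps
#' individuals observed in at least `min_years` different years, takes only
#' the first assay per year, and treats years as the repeated observations.
#'
#' @param table assay table.
#' @param years years to fit (default: all years with replicated
#'   individuals).
#' @param response one or two trait columns.
#' @param control an [mcmc_control()].
#' @param min_years minimum number of years an individual must appear in.
#' @return `within_year_fits()`: named list of `"vc_fit"` objects;
#'   `between_year_fit()`: a single `"vc_fit"`.
#' @export
within_year_fits <- function(table, response, years = NULL,
                             control = mcmc_control()) {
  .check_assay_table(table)
  if (is.null(years)) {
    has_reps <- vapply(split(table, table$year), function(s) {
      r <- table(s$individual_id[!is.na(s$individual_id)])
      sum(r >= 2L) >= 2L
    }, logical(1))
    years <- names(has_reps)[has_reps]
  }
  fits <- lapply(years, function(y)
    vc_mcmc(table[table$year == y, , drop = FALSE], response,
            control = control))
  stats::setNames(fits, years)
}

#' @rdname within_year_fits
#' @export
between_year_fit <- function(table, response, control = mcmc_control(),
                             min_years = 2L) {
  .check_assay_table(table)
  first <- first_assays(table)
  first <- first[!is.na(first$individual_id), , drop = FALSE]
  ny <- rowsum(rep(1L, nrow(first)), first$individual_id)
  keep <- rownames(ny)[ny[, 1] >= min_years]
  if (length(keep) < 2L)
    stop("repeatability unidentified: fewer than two individuals observed ",
         "in ", min_years, " or more years")
  vc_mcmc(first[first$individual_id %in% keep, , drop = FALSE], response,
          control = control)
}

#' Repeatability table across contexts
#'
#' Assembles the within-year fits and the between-year fit of one trait into
#' a single table (context, sample sizes, posterior mean and 95% credible
#' interval).
#'
#' @param within named list from [within_year_fits()] (univariate fits).
#' @param between a `"vc_fit"` from [between_year_fit()] (or `NULL`).
#' @return data frame with columns `context`, `n_individuals`,
#'   `n_observations`, `R`, `R_lo`, `R_hi`, `psrf`.
#' @export
repeatability_table <- function(within, between = NULL) {
  row1 <- function(ctx, fit) {
    s <- repeatability(fit)
    data.frame(context = ctx, n_individuals = fit$n_individuals,
               n_observations = fit$n_observations,
               R = s$mean[1], R_lo = s$lo95[1], R_hi = s$hi95[1],
               psrf = s$psrf[1], stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, Map(row1, names(within), within))
  if (!is.null(between)) out <- rbind(out, row1("between", between))
  rownames(out) <- NULL
  out
}
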