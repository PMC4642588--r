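#' Random-effects meta-analysis of Fisher-Z effect sizes
#'
#' Fits a random-effects model to year-specific effect sizes by
#' DerSimonian-Laird method-of-moments (default) or REML. With an
#' intercept-only formula this is the classic random-effects pool: each year
#' is treated as its own study with sampling variance `vi`, the
#' between-year variance `tau2` is estimated from the heterogeneity
#' statistic Q, and the pooled effect uses weights `1 / (vi + tau2)`. With
#' moderators on the right-hand side the same machinery gives a
#' meta-regression: weighted least squares with method-of-moments residual
#' `tau2` and a Wald omnibus test (`Q_M`) on the non-intercept terms.
#'
#' Confidence intervals and p-values use the normal approximation, matching
#' the arithmetic of back-transformed intervals
#' `tanh(z +/- 1.96 * se)` on the correlation scale.
#'
#' @param formula model formula; the response is the Fisher-Z effect size
#'   (e.g. `z ~ 1` for a plain pool, `z ~ age_structure` for a
#'   meta-regression).
#' @param vi sampling variances of the effect sizes (column of `data` or a
#'   numeric vector); all must be positive.
#' @param data data frame holding the effect sizes and moderators, e.g. the
#'   output of [year_effect_sizes()] merged with a moderator table.
#' @param method `"DL"` (method of moments) or `"REML"`.
#' @param level confidence level (default 0.95).
#' @return An object of class `"re_meta"` with components `b` (coefficients),
#'   `se`, `zval`, `pval`, `ci.lb`, `ci.ub`, `tau2`, `Q`, `df_Q`, `p_Q`,
#'   `I2`, `QM`, `df_QM`, `p_QM`, `k`, `p`, `yi`, `vi`, `X`, `vb`
#'   (coefficient covariance), plus `pooled_z`, `pooled_r` and `ci95_r` for
#'   intercept-only fits.
#' @seealso [heterogeneity()], [compare_pooled()], [p_from_estimate_ci()]
#' @examples
#' es <- data.frame(z = c(0.2, 0.35, 0.1, 0.4), var_z = 1 / (c(20, 35, 28, 40) - 3))
#' fit <- re_meta(z ~ 1, vi = var_z, data = es)
#' summary(fit)
#' @export
re_meta <- function(formula, vi, data, method = c("DL", "REML"),
                    level = 0.95) {
  method <- match.arg(method)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  vi <- eval(substitute(vi), data, parent.frame())
  if (is.null(vi)) stop("sampling variances 'vi' are required")
  vi <- as.numeric(vi)
  k <- length(y)
  p <- ncol(X)
  if (k < 1L) stop("no effect sizes to pool")
  if (length(vi) != k) stop("'vi' must match the number of effect sizes")
  if (any(vi <= 0)) stop("all sampling variances must be positive")
  if (k <= p && !(k == 1L && p == 1L))
    stop("need more effect sizes (", k, ") than coefficients (", p, ")")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("moderator design is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  # fixed-effect (inverse-variance) fit gives the heterogeneity statistic
  w <- 1 / vi
  fe <- .wls(X, y, w)
  Q <- sum(w * (y - X %*% fe$b)^2)
  df_Q <- k - p
  p_Q <- if (df_Q > 0) stats::pchisq(Q, df_Q, lower.tail = FALSE) else NA_real_

  tau2 <- switch(method,
    DL = .tau2_dl(X, y, w, Q, df_Q),
    REML = .tau2_reml(X, y, vi))

  ws <- 1 / (vi + tau2)
  fit <- .wls(X, y, ws)
  b <- drop(fit$b)
  vb <- fit$vb
  se <- sqrt(diag(vb))
  zval <- b / se
  pval <- 2 * stats::pnorm(abs(zval), lower.tail = FALSE)
  crit <- stats::qnorm(1 - (1 - level) / 2)
  ci.lb <- b - crit * se
  ci.ub <- b + crit * se

  # typical within-study variance; I2 on the tau2 scale
  s2 <- (k - 1) * sum(w) / (sum(w)^2 - sum(w^2))
  I2 <- if (k > 1) 100 * tau2 / (tau2 + s2) else 0

  # omnibus Wald test on the non-intercept coefficients
  mod_idx <- which(colnames(X) != "(Intercept)")
  if (length(mod_idx)) {
    bm <- b[mod_idx]
    QM <- drop(t(bm) %*% solve(vb[mod_idx, mod_idx, drop = FALSE]) %*% bm)
    df_QM <- length(mod_idx)
    p_QM <- stats::pchisq(QM, df_QM, lower.tail = FALSE)
  } else {
    QM <- NA_real_; df_QM <- 0L; p_QM <- NA_real_
  }

  out <- list(b = b, se = se, zval = zval, pval = pval,
              ci.lb = ci.lb, ci.ub = ci.ub, vb = vb,
              tau2 = tau2, Q = Q, df_Q = df_Q, p_Q = p_Q, I2 = I2,
              QM = QM, df_QM = df_QM, p_QM = p_QM,
              k = k, p = p, yi = y, vi = vi, X = X,
              method = method, level = level,
              formula = formula, intercept_only = (p == 1L &&
                colnames(X)[1] == "(Intercept)"))
  if (out$intercept_only) {
    out$pooled_z <- b[[1]]
    out$se_z <- se[[1]]
    out$pooled_r <- tanh(b[[1]])
    out$ci95_r <- tanh(c(ci.lb[[1]], ci.ub[[1]]))
    out$p_two_sided <- pval[[1]]
  }
  class(out) <- "re_meta"
  out
}

.wls <- function(X, y, w) {
  XtW <- t(X * w)
  vb <- solve(XtW %*% X)
  list(b = vb %*% (XtW %*% y), vb = vb)
}

# DerSimonian-Laird / method-of-moments tau2 for an arbitrary design:
# E[Q] = df + tau2 * tr(P), P = W - W X (X'WX)^-1 X'W with W = diag(1/vi)
.tau2_dl <- function(X, y, w, Q, df_Q) {
  if (df_Q <= 0) return(0)
  WX <- X * w
  trP <- sum(w) - sum(diag(solve(t(X) %*% WX) %*% (t(WX) %*% WX)))
  max(0, (Q - df_Q) / trP)
}

.tau2_reml <- function(X, y, vi, upper = NULL) {
  if (length(y) <= ncol(X)) return(0)
  if (is.null(upper)) upper <- max(10 * stats::var(y), 1e-3)
  nll <- function(tau2) {
    w <- 1 / (vi + tau2)
    fit <- .wls(X, y, w)
    res <- y - X %*% fit$b
    0.5 * (sum(log(vi + tau2)) + log(det(t(X * w) %*% X)) +
             sum(w * res^2))
  }
  opt <- stats::optimize(nll, c(0, upper))
  # guard against the optimum sitting at the boundary of the search range
  if (opt$minimum > 0.95 * upper)
    opt <- stats::optimize(nll, c(0, upper * 100))
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' @export
print.re_meta <- function(x, digits = 4, ...) {
  if (x$intercept_only) {
    cat("Random-effects pool (", x$method, ") of ", x$k, " effect sizes\n",
        sep = "")
    cat(sprintf("  pooled r = %.*f  (95%% CI %.*f / %.*f), p = %.4g\n",
                digits, x$pooled_r, digits, x$ci95_r[1], digits,
                x$ci95_r[2], x$p_two_sided))
    cat(sprintf("  tau2 = %.*f, Q = %.*f (df = %d, p = %.4g), I2 = %.2f%%\n",
                digits, x$tau2, digits, x$Q, x$df_Q, x$p_Q, x$I2))
  } else {
    cat("Meta-regression (", x$method, "), k = ", x$k, " effect sizes, ",
        x$p, " coefficients\n", sep = "")
    tab <- data.frame(estimate = x$b, se = x$se, z = x$zval, p = x$pval,
                      ci.lb = x$ci.lb, ci.ub = x$ci.ub)
    print(round(tab, digits))
    cat(sprintf("  residual tau2 = %.*f; QM = %.*f (df = %d, p = %.4g)\n",
                digits, x$tau2, digits, x$QM, x$df_QM, x$p_QM))
  }
  invisible(x)
}

#' @export
summary.re_meta <- function(object, ...) {
  object
}

#' @export
coef.re_meta <- function(object, ...) object$b

#' @export
vcov.re_meta <- function(object, ...) object$vb

#' Model-implied effects at new moderator values
#'
#' @param object a fitted [re_meta()] model.
#' @param newdata data frame of moderator values; omit for the fitted data.
#' @param ... unused.
#' @return data frame with the implied Fisher-Z effect (`z`), its standard
#'   error, confidence bounds, and the back-transformed correlation (`r`,
#'   `r.lb`, `r.ub`).
#' @export
predict.re_meta <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    Xn <- object$X
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    Xn <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  }
  zhat <- drop(Xn %*% object$b)
  se <- sqrt(rowSums((Xn %*% object$vb) * Xn))
  crit <- stats::qnorm(1 - (1 - object$level) / 2)
  data.frame(z = zhat, se = se,
             z.lb = zhat - crit * se, z.ub = zhat + crit * se,
             r = tanh(zhat), r.lb = tanh(zhat - crit * se),
             r.ub = tanh(zhat + crit * se))
}

#' @export
residuals.re_meta <- function(object, ...) {
  drop(object$yi - object$X %*% object$b)
}

#' Forest / moderator plot for a meta-analytic fit
#'
#' Intercept-only fits get a forest plot on the correlation scale (squares
#' sized by inverse variance, diamond for the pooled effect); fits with a
#' single moderator get a scatter of year effects against the moderator with
#' the model-implied regression line.
#'
#' @param x a fitted [re_meta()] model.
#' @param labels optional study (year) labels.
#' @param ... passed to the underlying plotting calls.
#' @export
plot.re_meta <- function(x, labels = NULL, ...) {
  crit <- stats::qnorm(1 - (1 - x$level) / 2)
  if (x$intercept_only) {
    k <- x$k
    r <- tanh(x$yi)
    lo <- tanh(x$yi - crit * sqrt(x$vi))
    hi <- tanh(x$yi + crit * sqrt(x$vi))
    if (is.null(labels)) labels <- paste("study", seq_len(k))
    ypos <- rev(seq_len(k))
    graphics::plot(NA, xlim = range(lo, hi, -1, 1), ylim = c(0, k + 1),
                   yaxt = "n", xlab = "correlation", ylab = "", ...)
    graphics::segments(lo, ypos, hi, ypos)
    graphics::points(r, ypos, pch = 15,
                     cex = 0.5 + (1 / x$vi) / max(1 / x$vi))
    graphics::axis(2, at = ypos, labels = labels, las = 1, cex.axis = 0.8)
    graphics::polygon(c(x$ci95_r[1], x$pooled_r, x$ci95_r[2], x$pooled_r),
                      c(0, 0.3, 0, -0.3) + 0.2, col = "grey40")
    graphics::abline(v = 0, lty = 3)
  } else if (x$p == 2L) {
    mod <- x$X[, 2]
    graphics::plot(mod, tanh(x$yi), xlab = colnames(x$X)[2],
                   ylab = "correlation", cex = 0.5 + (1 / x$vi) / max(1 / x$vi),
                   ...)
    xs <- seq(min(mod), max(mod), length.out = 100)
    nd <- stats::setNames(data.frame(xs), colnames(x$X)[2])
    pr <- predict.re_meta(x, nd)
    graphics::lines(xs, pr$r)
    graphics::abline(h = 0, lty = 3)
  } else {
    stop("no default plot for multi-moderator fits")
  }
  invisible(x)
}

#' Heterogeneity of a set of effect sizes
#'
#' Cochran's Q with inverse-variance weights, its p-value, the
#' method-of-moments `tau2`, and `I2 = 100 * tau2 / (tau2 + s2)` with `s2`
#' the typical within-study variance `(k-1) * sum(w) / ((sum(w))^2 - sum(w^2))`.
#'
#' @param z Fisher-Z effect sizes (or an `"effect_sizes"` data frame, in
#'   which case `var_z` is taken from it).
#' @param var_z sampling variances.
#' @return list with `Q`, `df`, `p_Q`, `tau2`, `I2`.
#' @export
heterogeneity <- function(z, var_z = NULL) {
  if (is.data.frame(z)) {
    var_z <- z$var_z
    z <- z$z
  }
  fit <- re_meta(z ~ 1, vi = var_z, data = data.frame(z = z, var_z = var_z))
  list(Q = fit$Q, df = fit$df_Q, p_Q = fit$p_Q, tau2 = fit$tau2, I2 = fit$I2)
}

#' Pool effect sizes separately for each trait pair
#'
#' @param effects an `"effect_sizes"` data frame covering one or more pairs.
#' @param ... passed to [re_meta()].
#' @return named list of `"re_meta"` fits, one per pair.
#' @export
pool_by_pair <- function(effects, ...) {
  pairs <- unique(effects$pair)
  fits <- lapply(pairs, function(p)
    re_meta(z ~ 1, vi = var_z, data = effects[effects$pair == p, ], ...))
  stats::setNames(fits, pairs)
}

#' Compare two pooled correlations
#'
#' Two-sample z test on the Fisher-Z scale:
#' `z = (atanh(r2) - atanh(r1)) / sqrt(1/(n1-3) + 1/(n2-3))` with a
#' two-sided normal p-value. Used to ask whether two pooled effect
#' magnitudes (e.g. the two consistently positive trait-pair correlations)
#' are statistically distinguishable.
#'
#' @param r1,r2 the two correlations.
#' @param n1,n2 their sample sizes (must exceed 3).
#' @return object of class `"htest"`.
#' @export
compare_pooled <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r2) - atanh(r1)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  structure(list(statistic = c(z = z), p.value = p,
                 estimate = c(r1 = r1, r2 = r2),
                 alternative = "two.sided",
                 method = "Comparison of two pooled correlations (Fisher-Z)",
                 data.name = sprintf("r1 = %g (n = %d), r2 = %g (n = %d)",
                                     r1, as.integer(n1), r2, as.integer(n2))),
            class = "htest")
}

#' Two-sided p-value implied by a correlation and its confidence interval
#'
#' Recovers the standard error on the Fisher-Z scale from a symmetric-on-Z
#' 95% confidence interval, `se = (atanh(hi) - atanh(lo)) / (2 * 1.96)`, and
#' returns the two-sided normal p-value for the null of zero correlation —
#' a consistency check on pooled estimates reported as `r` with a CI.
#'
#' @param r point estimate of the correlation.
#' @param ci_lo,ci_hi confidence bounds (must bracket `r`).
#' @return the two-sided p-value.
#' @export
p_from_estimate_ci <- function(r, ci_lo, ci_hi) {
  if (!(ci_lo < r && r < ci_hi)) stop("interval must bracket the estimate")
  se <- (atanh(ci_hi) - atanh(ci_lo)) / (2 * stats::qnorm(0.975))
  2 * stats::pnorm(abs(atanh(r) / se), lower.tail = FALSE)
}
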