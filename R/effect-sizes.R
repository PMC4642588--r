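#' Midranks of a numeric vector
#'
#' Average ranks with ties sharing their midrank — the convention under which
#' blocks of censored latencies (all recorded at the 301-s ceiling) receive
#' identical ranks. Missing values are excluded from ranking and returned as
#' `NA`, with the count of exclusions attached as attribute `"n_missing"`.
#'
#' @param values numeric vector with at least one finite value.
#' @return numeric vector of midranks, same length as `values`.
#' @export
rank_with_ties <- function(values) {
  if (!any(is.finite(values))) stop("no finite values to rank")
  r <- rep(NA_real_, length(values))
  ok <- !is.na(values)
  r[ok] <- rank(values[ok], ties.method = "average")
  attr(r, "n_missing") <- sum(!ok)
  r
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks over pairwise-complete observations.
#'
#' @param x,y numeric vectors of equal length; at least 4 pairwise-complete
#'   pairs are required.
#' @return the correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 4L) stop("need at least 4 pairwise-complete observations")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant vector")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Fisher's Z transform and its inverse
#'
#' `fisher_z()` maps a correlation to `atanh(r)`; correlations are clamped at
#' `|r| <= 0.9999` first so degenerate (perfect) correlations keep finite
#' meta-analytic weights. `inv_fisher_z()` is `tanh(z)`.
#'
#' @param r correlation(s) in \[-1, 1\].
#' @param z Fisher-Z value(s).
#' @return transformed numeric vector.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("correlations must lie in [-1, 1]")
  atanh(pmin(pmax(r, -0.9999), 0.9999))
}

#' @rdname fisher_z
#' @export
inv_fisher_z <- function(z) tanh(z)

#' Year-by-pair correlation effect sizes from an assay table
#'
#' Computes, for every year and every trait pair (NA-AG, NA-RT, AG-RT), the
#' Spearman rank correlation of the first-assay scores, its Fisher-Z value
#' and the sampling variance `1 / (n - 3)` with `n` the pairwise-complete
#' sample size for that pair in that year. Only first assays enter (one
#' observation per bird); years contributing fewer than `min_n` complete
#' pairs are dropped with a warning.
#'
#' With all traits stored so that smaller = bolder, a positive correlation
#' means that birds bold in one assay tend to be bold in the other.
#'
#' @param table assay table (see [simulate_assays()]).
#' @param pairs character vector of pairs to compute (subset of
#'   `"NA-AG"`, `"NA-RT"`, `"AG-RT"`).
#' @param min_n minimum pairwise-complete sample size for a year to be kept
#'   (default 5, matching the field study's exclusion of a season with fewer
#'   than five assayed males).
#' @return A data frame of class `"effect_sizes"` with columns
#'   `year`, `pair`, `n`, `r`, `z`, `var_z`.
#' @export
year_effect_sizes <- function(table, pairs = .trait_pairs, min_n = 5L) {
  .check_assay_table(table)
  pairs <- match.arg(pairs, .trait_pairs, several.ok = TRUE)
  first <- first_assays(table)
  out <- list()
  dropped <- character(0)
  for (y in unique(first$year)) {
    sub <- first[first$year == y, ]
    for (p in pairs) {
      cols <- .pair_columns(p)
      ok <- !is.na(sub[[cols[1]]]) & !is.na(sub[[cols[2]]])
      n <- sum(ok)
      if (n < min_n) {
        dropped <- union(dropped, paste0(y, "/", p, " (n=", n, ")"))
        next
      }
      r <- spearman_rho(sub[[cols[1]]], sub[[cols[2]]])
      out[[length(out) + 1L]] <- data.frame(
        year = y, pair = p, n = n, r = r, z = fisher_z(r),
        var_z = 1 / (n - 3), stringsAsFactors = FALSE)
    }
  }
  if (length(dropped))
    warning("dropped year/pair cells below the minimum sample size: ",
            paste(dropped, collapse = ", "))
  if (!length(out)) stop("no year/pair cell reached the minimum sample size")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("effect_sizes", "data.frame")
  res
}

#' Write / read an effect-size table as TSV
#'
#' @param effects an `"effect_sizes"` data frame.
#' @param file path to the TSV file.
#' @return `write_effect_tsv` returns `file` invisibly; `read_effect_tsv`
#'   returns the effect-size table.
#' @export
write_effect_tsv <- function(effects, file) {
  utils::write.table(effects, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_effect_tsv
#' @export
read_effect_tsv <- function(file) {
  res <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = c(year = "character"))
  class(res) <- c("effect_sizes", "data.frame")
  res
}
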