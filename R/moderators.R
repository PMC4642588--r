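#' Per-day competition index for nest-box breeders
#'
#' Relative density — breeding efforts divided by available nest-boxes —
#' corrected for breeding synchrony: the density is divided by the length in
#' days of the interval within which 90% of breeding efforts occurred,
#' giving average competition per day. By default the interval is the
#' SHORTEST window containing at least the required fraction of breeding
#' initiation dates; a central quantile window (5th-95th percentile for 90%
#' coverage) is available via `interval`.
#'
#' @param breeding_efforts number of breeding efforts (count).
#' @param available_boxes number of available nest-boxes (count > 0).
#' @param breeding_dates integer day-of-season of each breeding initiation
#'   (length >= 1).
#' @param coverage fraction of efforts the window must contain (default 0.9).
#' @param interval `"shortest"` (default) or `"central"`.
#' @return the per-day competition index
#'   `(efforts / boxes) / interval_days`, with the window length (days,
#'   at least 1) attached as attribute `"interval_days"`.
#' @export
competition_index <- function(breeding_efforts, available_boxes,
                              breeding_dates, coverage = 0.9,
                              interval = c("shortest", "central")) {
  interval <- match.arg(interval)
  if (available_boxes <= 0) stop("available_boxes must be positive")
  if (!length(breeding_dates)) stop("at least one breeding date is required")
  if (coverage <= 0 || coverage > 1) stop("coverage must lie in (0, 1]")
  days <- if (interval == "shortest")
    shortest_window(breeding_dates, coverage)
  else {
    tail_p <- (1 - coverage) / 2
    qs <- stats::quantile(breeding_dates, c(tail_p, 1 - tail_p), type = 1)
    max(1, qs[[2]] - qs[[1]] + 1)
  }
  structure((breeding_efforts / available_boxes) / days,
            interval_days = days)
}

#' Shortest window covering a fraction of dates
#'
#' Length in days (inclusive, minimum 1) of the shortest window containing
#' at least `ceiling(coverage * n)` of the supplied dates.
#'
#' @param dates integer dates (day-of-season).
#' @param coverage required fraction in (0, 1].
#' @return window length in days.
#' @export
shortest_window <- function(dates, coverage = 0.9) {
  d <- sort(dates)
  n <- length(d)
  m <- ceiling(coverage * n)
  if (m <= 1L) return(1)
  starts <- seq_len(n - m + 1L)
  max(1, min(d[starts + m - 1L] - d[starts]) + 1)
}

#' Age structure of the assayed sample
#'
#' @param n_juvenile number of juvenile males.
#' @param n_total total number of assayed males (> 0, >= `n_juvenile`).
#' @return proportion of juveniles in \[0, 1\].
#' @export
age_structure <- function(n_juvenile, n_total) {
  if (any(n_total <= 0)) stop("n_total must be positive")
  if (any(n_juvenile < 0 | n_juvenile > n_total))
    stop("n_juvenile must lie in [0, n_total]")
  n_juvenile / n_total
}

#' Lag a predation-rate series by one year
#'
#' Behavioral correlations in year `y` are matched with the predation rate
#' of year `y - 1` (nest predation happens after the courtship assays, so
#' it can only influence behavior the following season). Years whose
#' previous year is absent from the series are dropped with a warning.
#'
#' @param years integer (or integer-like) years.
#' @param rates predation rates in \[0, 1\], parallel to `years`.
#' @return named numeric vector: previous-year rate for each retained year.
#' @export
lag_predation <- function(years, rates) {
  if (length(years) != length(rates)) stop("years and rates must match")
  years <- as.integer(as.character(years))
  prev <- match(years - 1L, years)
  keep <- !is.na(prev)
  if (!any(keep)) {
    warning("no year has a previous-year predation rate; empty result")
    return(stats::setNames(numeric(0), character(0)))
  }
  if (any(!keep))
    warning("dropped year(s) without a previous-year rate: ",
            paste(years[!keep], collapse = ", "))
  stats::setNames(rates[prev[keep]], years[keep])
}

#' Square-root transform proportion moderators
#'
#' @param x proportions in \[0, 1\] (vector, or data frame whose listed
#'   columns are transformed).
#' @param columns for the data-frame method, columns to transform.
#' @return transformed vector or data frame.
#' @export
sqrt_transform <- function(x, columns = NULL) {
  if (is.data.frame(x)) {
    for (col in columns) x[[col]] <- sqrt_transform(x[[col]])
    return(x)
  }
  if (any(x < 0, na.rm = TRUE))
    stop("square-root transform is undefined for negative values")
  sqrt(x)
}

#' Screen moderators for collinearity
#'
#' Pairwise Pearson correlations among moderator columns; any pair with
#' `|r|` above the threshold is flagged for exclusion from multivariate
#' meta-regression (only one member of a flagged pair should enter).
#'
#' @param X numeric matrix or data frame of moderators.
#' @param threshold absolute-correlation flag threshold (default 0.8).
#' @return data frame with `var1`, `var2`, `r`, `flagged`.
#' @export
collinearity_screen <- function(X, threshold = 0.8) {
  X <- as.data.frame(X)
  nm <- names(X)
  if (length(nm) < 2L) stop("need at least two moderator columns")
  out <- list()
  for (i in seq_len(length(nm) - 1L)) {
    for (j in seq((i + 1L), length(nm))) {
      r <- stats::cor(X[[i]], X[[j]], use = "pairwise.complete.obs")
      out[[length(out) + 1L]] <- data.frame(
        var1 = nm[i], var2 = nm[j], r = r,
        flagged = is.finite(r) && abs(r) > threshold,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble the year-level moderator table
#'
#' From raw year-level inputs, builds the four socio-ecological moderators
#' on the scale used by the meta-regression: mean daily temperature
#' (passthrough), previous-year predation rate, per-day competition index,
#' and proportion of juveniles — the three proportion-based moderators
#' square-root transformed (`*_sqrt` columns).
#'
#' @param raw data frame with columns `year`, `mean_temp_c`,
#'   `predation_rate` (same-year; lagging is applied here),
#'   `breeding_efforts`, `available_boxes`, `n_juvenile`, `n_total`, and
#'   either `interval_days` or a list-column `breeding_dates` of date
#'   vectors.
#' @param coverage,interval passed to [competition_index()] when breeding
#'   dates are supplied.
#' @return data frame of class `"moderator_table"`: `year`, `mean_temp`,
#'   `predation_prev`, `competition`, `prop_juvenile`, plus
#'   `predation_prev_sqrt`, `competition_sqrt`, `prop_juvenile_sqrt`.
#'   Years without a previous-year predation rate carry `NA` there.
#' @export
moderator_table <- function(raw, coverage = 0.9,
                            interval = c("shortest", "central")) {
  interval <- match.arg(interval)
  need <- c("year", "mean_temp_c", "predation_rate", "breeding_efforts",
            "available_boxes", "n_juvenile", "n_total")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("moderator input is missing column(s): ",
         paste(miss, collapse = ", "))
  if (any(raw$predation_rate < 0 | raw$predation_rate > 1, na.rm = TRUE))
    stop("predation_rate must lie in [0, 1]")
  comp <- vapply(seq_len(nrow(raw)), function(i) {
    if (!is.null(raw$breeding_dates))
      as.numeric(competition_index(raw$breeding_efforts[i],
                                   raw$available_boxes[i],
                                   raw$breeding_dates[[i]],
                                   coverage, interval))
    else if (!is.null(raw$interval_days))
      (raw$breeding_efforts[i] / raw$available_boxes[i]) /
        max(1, raw$interval_days[i])
    else stop("supply either breeding_dates or interval_days")
  }, numeric(1))
  yrs <- as.integer(as.character(raw$year))
  prev <- suppressWarnings(lag_predation(yrs, raw$predation_rate))
  out <- data.frame(
    year = as.character(raw$year),
    mean_temp = raw$mean_temp_c,
    predation_prev = unname(prev[as.character(yrs)]),
    competition = comp,
    prop_juvenile = age_structure(raw$n_juvenile, raw$n_total),
    stringsAsFactors = FALSE)
  out$predation_prev_sqrt <- sqrt_transform(out$predation_prev)
  out$competition_sqrt <- sqrt_transform(out$competition)
  out$prop_juvenile_sqrt <- sqrt_transform(out$prop_juvenile)
  class(out) <- c("moderator_table", "data.frame")
  out
}

#' Read a raw moderator CSV
#'
#' Expected columns: `year, mean_temp_c, predation_rate, breeding_efforts,
#' available_boxes, interval_days, n_juvenile, n_total` (or
#' `breeding_dates_file` pointing to a two-column CSV `year, date` of
#' breeding initiation dates, from which the synchrony interval is
#' computed).
#'
#' @param file path to the CSV.
#' @param ... passed to [moderator_table()].
#' @return a `"moderator_table"`.
#' @export
read_moderator_csv <- function(file, ...) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!is.null(raw$breeding_dates_file)) {
    dates <- utils::read.csv(file.path(dirname(file),
                                       raw$breeding_dates_file[1]),
                             stringsAsFactors = FALSE)
    raw$breeding_dates <- lapply(raw$year, function(y)
      dates$date[dates$year == y])
  }
  moderator_table(raw, ...)
}
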