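#' Simulate a multi-year repeated behavioral assay table
#'
#' Draws a long-format assay table from the hierarchical model described by a
#' [truth_config()]: per year, individual intercepts `b_i ~ MVN(0, sigma_ind)`
#' and residuals `e_ij ~ MVN(0, sigma_e)` give observations
#' `y_ij = mu + date_slopes * date_ij + b_i + e_ij` on the three traits.
#' Aggression latencies are censored at the configured ceiling (recorded at
#' the ceiling and flagged), novelty-avoidance differences are clamped at
#' plus/minus the ceiling, capture is drawn from the logistic capture model
#' applied to the standardized first-assay scores, and only captured birds
#' receive repeat assays (their repeat count is drawn from the year's
#' repeats distribution). Non-captured birds lose their identity (missing
#' `individual_id`) and are never re-assayed.
#'
#' Each year uses an independent RNG substream derived from the seed and the
#' year label, so adding or dropping a year leaves the remaining years'
#' draws untouched.
#'
#' @param config a [truth_config()].
#' @return A `data.frame` with columns `year`, `individual_id`,
#'   `assay_order`, `assay_date`, `novelty_avoidance_s`,
#'   `aggression_latency_s`, `fid_m`, `captured`, `age_class`,
#'   `censored_aggression`. The ground truth is attached as attribute
#'   `"truth"`.
#' @export
simulate_assays <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  out <- lapply(config$years, function(y) .simulate_year(config, y))
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  attr(tab, "truth") <- config
  tab
}

# deterministic per-year substream seed from (seed, year label)
.year_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * 31^(seq_along(codes) - 1)) %% 1000003
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483587) + 1L
}

.simulate_year <- function(config, year) {
  set.seed(.year_seed(config$seed, year))
  n <- config$n_individuals[[year]]
  si <- config$sigma_ind[[year]]
  se <- config$sigma_e[[year]]
  thr <- config$censor_threshold

  b <- .rmvn(n, si)                       # individual intercepts, n x 3
  date1 <- sample.int(config$season_length, n, replace = TRUE)
  age <- ifelse(stats::runif(n) < config$prop_juvenile[[year]],
                "juvenile", "adult")

  first <- .draw_assays(config, year, b, date1, se)

  # capture from the observed (censored) first-assay scores
  p_cap <- .capture_prob(first$y, config$capture_model)
  captured <- stats::runif(n) < p_cap

  # repeat counts for captured birds only
  rd <- config$repeats_distribution[[year]]
  supp <- as.integer(names(rd))
  n_assays <- rep(1L, n)
  if (any(captured))
    n_assays[captured] <- supp[sample.int(length(supp), sum(captured),
                                          replace = TRUE, prob = rd)]

  ids <- sprintf("%s_%03d", year, seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- n_assays[i]
    if (k > 1L) {
      gaps <- sample.int(4L, k - 1L, replace = TRUE)
      dates <- date1[i] + c(0L, cumsum(gaps))
      more <- .draw_assays(config, year, b[rep(i, k - 1L), , drop = FALSE],
                           dates[-1L], se)
      yk <- rbind(first$y[i, , drop = FALSE], more$y)
      cens <- c(first$censored[i], more$censored)
    } else {
      dates <- date1[i]
      yk <- first$y[i, , drop = FALSE]
      cens <- first$censored[i]
    }
    rows[[i]] <- data.frame(
      year = year,
      individual_id = if (captured[i]) ids[i] else NA_character_,
      assay_order = seq_len(k),
      assay_date = dates,
      novelty_avoidance_s = yk[, 1],
      aggression_latency_s = yk[, 2],
      fid_m = yk[, 3],
      captured = captured[i],
      age_class = age[i],
      censored_aggression = cens,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# draw one assay row per (b, date) pair and apply censoring/clamping
.draw_assays <- function(config, year, b, dates, sigma_e) {
  m <- nrow(b)
  e <- .rmvn(m, sigma_e)
  y <- sweep(b + e, 2, config$mu, "+") +
    outer(dates, config$date_slopes)
  thr <- config$censor_threshold
  censored <- y[, 2] >= thr
  y[, 2] <- pmin(pmax(y[, 2], 1), thr)      # latency in (0, thr]
  y[, 1] <- pmin(pmax(y[, 1], -thr), thr)   # latency difference clamp
  y[, 3] <- pmax(y[, 3], 0.1)               # distance > 0
  list(y = y, censored = censored)
}

# multivariate normal via eigendecomposition (tolerates PSD rank deficiency)
.rmvn <- function(n, sigma) {
  p <- ncol(sigma)
  ev <- eigen((sigma + t(sigma)) / 2, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  z <- matrix(stats::rnorm(n * p), n, p)
  z %*% (t(ev$vectors) * sqrt(lam))
}

# logistic capture probability from standardized oriented scores
.capture_prob <- function(scores, model) {
  z <- scale(scores)
  z[, apply(scores, 2, function(v) stats::sd(v) == 0 || !is.finite(stats::sd(v)))] <- 0
  z[!is.finite(z)] <- 0
  eta <- model$intercept + drop(z %*% model$slopes)
  stats::plogis(eta)
}

#' Apply behavior-dependent capture bias to an assay table
#'
#' Redraws the `captured` flag from a logistic model of the standardized
#' behavior scores on each bird's first assay. Birds that end up
#' non-captured lose their identity (`individual_id` set to missing) and
#' their repeat assays are removed — in the field, a bird that was never
#' caught can never be recognized again. With negative slopes (traits are
#' stored so that smaller = bolder), shy birds are harder to capture and the
#' identified subsample is bolder than the full sample.
#'
#' @param table an assay table as returned by [simulate_assays()].
#' @param capture_model list with `intercept` and length-3 `slopes` (order:
#'   novelty avoidance, aggression latency, FID).
#' @param seed optional integer seed; if `NULL` the current RNG state is used.
#' @return The assay table with updated `captured`, `individual_id` and rows.
#' @export
apply_capture_bias <- function(table, capture_model, seed = NULL) {
  .check_assay_table(table)
  if (!is.null(seed)) set.seed(seed)
  first <- table[table$assay_order == 1L, ]
  scores <- as.matrix(first[, c("novelty_avoidance_s", "aggression_latency_s",
                                "fid_m")])
  p <- .capture_prob(scores, capture_model)
  cap <- stats::runif(nrow(first)) < p

  first$captured <- cap
  # rebuild: captured birds keep all their rows, others keep first row, no id
  out <- vector("list", nrow(first))
  for (i in seq_len(nrow(first))) {
    if (cap[i] && !is.na(first$individual_id[i])) {
      rows <- table[!is.na(table$individual_id) &
                      table$individual_id == first$individual_id[i] &
                      table$year == first$year[i], ]
      rows$captured <- TRUE
    } else {
      rows <- first[i, ]
      rows$individual_id <- NA_character_
      rows$captured <- FALSE
      rows$assay_order <- 1L
    }
    out[[i]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- attr(table, "truth")
  res
}

.assay_columns <- c("year", "individual_id", "assay_order", "assay_date",
                    "novelty_avoidance_s", "aggression_latency_s", "fid_m",
                    "captured", "age_class", "censored_aggression")

.check_assay_table <- function(table) {
  miss <- setdiff(.assay_columns, names(table))
  if (length(miss))
    stop("assay table is missing columns: ", paste(miss, collapse = ", "))
  invisible(table)
}

#' Write / read an assay table as CSV
#'
#' The on-disk schema has exactly the columns
#' `year, individual_id, assay_order, assay_date, novelty_avoidance_s,
#' aggression_latency_s, fid_m, captured, age_class, censored_aggression`;
#' missing identities are encoded as empty fields. The round trip is
#' lossless (numeric fields are written with 15 significant digits).
#'
#' @param table assay table (see [simulate_assays()]).
#' @param file path to the CSV file.
#' @return `write_assay_csv` returns `file` invisibly; `read_assay_csv`
#'   returns the assay table. Malformed numeric fields and unknown columns
#'   raise errors naming the offending lines or columns.
#' @export
write_assay_csv <- function(table, file) {
  .check_assay_table(table)
  out <- table[, .assay_columns]
  for (col in c("novelty_avoidance_s", "aggression_latency_s", "fid_m"))
    out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
  out$captured <- ifelse(out$captured, "TRUE", "FALSE")
  out$censored_aggression <- ifelse(out$censored_aggression, "TRUE", "FALSE")
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE, na = "")
  invisible(file)
}

#' @rdname write_assay_csv
#' @export
read_assay_csv <- function(file) {
  raw <- utils::read.csv(file, colClasses = "character", na.strings = NULL,
                         check.names = FALSE)
  extra <- setdiff(names(raw), .assay_columns)
  if (length(extra))
    stop("unknown column(s) in assay CSV: ", paste(extra, collapse = ", "))
  miss <- setdiff(.assay_columns, names(raw))
  if (length(miss))
    stop("assay CSV is missing column(s): ", paste(miss, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & nzchar(raw[[col]]))
    if (length(bad))
      stop("malformed numeric field '", col, "' on line(s) ",
           paste(bad + 1L, collapse = ", "))
    v
  }
  lgl <- function(col) {
    ok <- raw[[col]] %in% c("TRUE", "FALSE")
    if (any(!ok))
      stop("malformed logical field '", col, "' on line(s) ",
           paste(which(!ok) + 1L, collapse = ", "))
    raw[[col]] == "TRUE"
  }
  data.frame(
    year = raw$year,
    individual_id = ifelse(nzchar(raw$individual_id), raw$individual_id,
                           NA_character_),
    assay_order = as.integer(num("assay_order")),
    assay_date = as.integer(num("assay_date")),
    novelty_avoidance_s = num("novelty_avoidance_s"),
    aggression_latency_s = num("aggression_latency_s"),
    fid_m = num("fid_m"),
    captured = lgl("captured"),
    age_class = raw$age_class,
    censored_aggression = lgl("censored_aggression"),
    stringsAsFactors = FALSE)
}

#' First assay per bird within each year
#'
#' Phenotypic correlations use one observation per bird: the assay taken on
#' arrival (`assay_order == 1`).
#'
#' @param table assay table.
#' @return The subset of rows with `assay_order == 1`.
#' @export
first_assays <- function(table) {
  .check_assay_table(table)
  table[table$assay_order == 1L, , drop = FALSE]
}
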