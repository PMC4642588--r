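#' Configuration for the end-to-end analysis pipeline
#'
#' Exactly one of `truth` (simulation mode) or `assay_csv` (file mode) must
#' be supplied.
#'
#' @param truth a [truth_config()] for simulation mode.
#' @param assay_csv path to an assay CSV (see [read_assay_csv()]).
#' @param moderator_csv optional path to a raw moderator CSV
#'   (see [read_moderator_csv()]); without it the meta-regression stage is
#'   skipped.
#' @param control an [mcmc_control()] for the variance-partition stages.
#' @param min_n minimum per-year sample size for effect sizes.
#' @param gate_p,gate_I2 heterogeneity gate: moderators are regressed only
#'   on pairs with `p_Q < gate_p` OR `I2 > gate_I2` (defaults 0.05 and 25) —
#'   meta-regression is only meaningful where effect sizes truly vary.
#' @param collinearity_threshold absolute correlation above which one of a
#'   moderator pair is dropped from the multivariate model.
#' @param level confidence level for meta-analytic intervals.
#' @param out_dir optional directory; when set, [run_pipeline()] writes the
#'   stage tables (TSV) and a JSON report there.
#' @param seed integer seed for every stochastic stage.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(truth = NULL, assay_csv = NULL,
                            moderator_csv = NULL,
                            control = mcmc_control(),
                            min_n = 5L, gate_p = 0.05, gate_I2 = 25,
                            collinearity_threshold = 0.8,
                            level = 0.95, out_dir = NULL, seed = 1L) {
  if (is.null(truth) == is.null(assay_csv))
    stop("supply exactly one of 'truth' (simulation) or 'assay_csv' (file)")
  structure(list(truth = truth, assay_csv = assay_csv,
                 moderator_csv = moderator_csv, control = control,
                 min_n = min_n, gate_p = gate_p, gate_I2 = gate_I2,
                 collinearity_threshold = collinearity_threshold,
                 level = level, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE))
}

#' Run the full among-year correlation pipeline
#'
#' Stage order: assay data (simulated or read) -> year-by-pair effect sizes
#' -> random-effects pool per pair -> heterogeneity gate -> meta-regression
#' on the socio-ecological moderators for gated pairs -> variance partition
#' (within-year and between-year repeatabilities) for years with repeated
#' measurements -> bivariate decomposition with reconstruction validation
#' -> weighted t tests and Fisher's combined probability. Stages that lack
#' their inputs (no repeats, no moderators) are skipped with a notice in
#' `$notices`.
#'
#' @param config a [pipeline_config()].
#' @return list of class `"syndrome_report"` with elements `assays`,
#'   `effects`, `meta` (per-pair [re_meta()] fits), `heterogeneity_gate`,
#'   `meta_regression`, `repeatability` (per-trait tables),
#'   `decomposition`, `reconstruction`, `weighted_tests`, `notices`,
#'   `seed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  notices <- character(0)
  note <- function(msg) notices <<- c(notices, msg)

  assays <- .stage("data", {
    if (!is.null(config$truth)) {
      truth <- config$truth
      truth$seed <- config$seed
      simulate_assays(truth)
    } else read_assay_csv(config$assay_csv)
  })

  moderators <- NULL
  if (!is.null(config$moderator_csv))
    moderators <- .stage("moderators", read_moderator_csv(config$moderator_csv))

  effects <- .stage("effects",
    suppressWarnings(year_effect_sizes(assays, min_n = config$min_n)))

  meta <- .stage("meta", pool_by_pair(effects, level = config$level))

  gate <- .stage("heterogeneity-gate", {
    data.frame(pair = names(meta),
               Q = vapply(meta, `[[`, numeric(1), "Q"),
               p_Q = vapply(meta, `[[`, numeric(1), "p_Q"),
               I2 = vapply(meta, `[[`, numeric(1), "I2"),
               gated = vapply(meta, function(f)
                 isTRUE(f$p_Q < config$gate_p) ||
                   isTRUE(f$I2 > config$gate_I2), logical(1)),
               row.names = NULL)
  })

  metareg <- NULL
  if (any(gate$gated) && !is.null(moderators)) {
    metareg <- .stage("meta-regression",
      .fit_moderators(effects, meta, gate, moderators, config))
  } else if (any(gate$gated)) {
    note("meta-regression skipped: no moderator table supplied")
  } else {
    note("meta-regression skipped: no pair passed the heterogeneity gate")
  }

  rep_years <- .years_with_repeats(assays)
  repeatab <- NULL; decomp <- NULL; recon <- NULL; wtests <- NULL
  if (length(rep_years) >= 2L) {
    repeatab <- .stage("variance-partition",
      .repeatability_stage(assays, rep_years, config))
    decomp <- .stage("decomposition",
      decompose_pairs(assays, years = rep_years, control = config$control,
                      min_n = config$min_n))
    recon <- .stage("reconstruction", {
      ok <- stats::complete.cases(decomp$r_P_expected, decomp$r_P_observed)
      if (sum(ok) >= 4L)
        reconstruction_validation(decomp$r_P_expected, decomp$r_P_observed)
      else NULL
    })
    wtests <- .stage("weighted-tests", .weighted_stage(repeatab))
  } else {
    note(paste0("variance partition, decomposition and weighted tests ",
                "skipped: fewer than two years with repeated measurements"))
  }

  report <- structure(
    list(assays = assays, effects = effects, meta = meta,
         heterogeneity_gate = gate, meta_regression = metareg,
         repeatability = repeatab, decomposition = decomp,
         reconstruction = recon, weighted_tests = wtests,
         moderators = moderators, notices = notices, seed = config$seed),
    class = "syndrome_report")
  if (!is.null(config$out_dir)) .write_report(report, config$out_dir)
  report
}

.years_with_repeats <- function(assays) {
  has <- vapply(split(assays, assays$year), function(s) {
    r <- table(s$individual_id[!is.na(s$individual_id)])
    sum(r >= 2L) >= 2L
  }, logical(1))
  names(has)[has]
}

.moderator_vars <- c("mean_temp", "predation_prev_sqrt", "competition_sqrt",
                     "prop_juvenile_sqrt")

.fit_moderators <- function(effects, meta, gate, moderators, config) {
  out <- list()
  for (pr in gate$pair[gate$gated]) {
    es <- merge(effects[effects$pair == pr, ], moderators, by = "year")
    vars <- .moderator_vars[.moderator_vars %in% names(es)]
    pairwise <- lapply(vars, function(v) {
      d <- es[stats::complete.cases(es[c("z", "var_z", v)]), ]
      re_meta(stats::reformulate(v, response = "z"), vi = var_z, data = d,
              level = config$level)
    })
    names(pairwise) <- vars
    screen <- collinearity_screen(es[vars],
                                  threshold = config$collinearity_threshold)
    drop_vars <- unique(screen$var2[screen$flagged])
    multi_vars <- setdiff(vars, drop_vars)
    d <- es[stats::complete.cases(es[c("z", "var_z", multi_vars)]), ]
    multivariate <- if (nrow(d) > length(multi_vars) + 1L)
      re_meta(stats::reformulate(multi_vars, response = "z"), vi = var_z,
              data = d, level = config$level)
    else NULL
    out[[pr]] <- list(pairwise = pairwise, multivariate = multivariate,
                      collinearity = screen, excluded = drop_vars)
  }
  out
}

.repeatability_stage <- function(assays, rep_years, config) {
  out <- list()
  for (tr in .traits) {
    within <- within_year_fits(assays, tr, years = rep_years,
                               control = config$control)
    between <- tryCatch(
      between_year_fit(assays, tr, control = config$control),
      error = function(e) NULL)
    out[[tr]] <- repeatability_table(within, between)
  }
  out
}

.weighted_stage <- function(repeatab) {
  one_sample <- list()
  for (tr in names(repeatab)) {
    tab <- repeatab[[tr]]
    within <- tab[tab$context != "between", ]
    between <- tab[tab$context == "between", ]
    if (nrow(between) && nrow(within) >= 2L)
      one_sample[[tr]] <- weighted_t_one_sample(
        within$R, within$n_individuals, mu0 = between$R)
  }
  paired <- list()
  trs <- names(repeatab)
  if (length(trs) >= 2L) {
    for (i in seq_len(length(trs) - 1L)) for (j in seq((i + 1L), length(trs))) {
      a <- repeatab[[trs[i]]]; b <- repeatab[[trs[j]]]
      a <- a[a$context != "between", ]; b <- b[b$context != "between", ]
      shared <- intersect(a$context, b$context)
      if (length(shared) >= 2L) {
        ia <- match(shared, a$context); ib <- match(shared, b$context)
        paired[[paste(trs[i], trs[j], sep = " vs ")]] <-
          weighted_t_paired(a$R[ia], b$R[ib],
                            pmin(a$n_individuals[ia], b$n_individuals[ib]))
      }
    }
  }
  combined <- if (length(one_sample) >= 2L)
    fisher_combined(vapply(one_sample, `[[`, numeric(1), "p.value"))
  else NULL
  list(one_sample = one_sample, paired = paired, combined = combined)
}

#' @export
print.syndrome_report <- function(x, ...) {
  cat("Among-year behavioral correlation report\n")
  cat("  assays:", nrow(x$assays), "rows,",
      length(unique(x$assays$year)), "years\n")
  cat("  pooled effects:\n")
  for (pr in names(x$meta)) {
    f <- x$meta[[pr]]
    cat(sprintf("    %s: r = %.3f (%.3f / %.3f), p = %.3g, I2 = %.1f%%\n",
                pr, f$pooled_r, f$ci95_r[1], f$ci95_r[2], f$p_two_sided,
                f$I2))
  }
  if (!is.null(x$reconstruction))
    cat(sprintf("  reconstruction validation: r = %.3f (p = %.3g)\n",
                unname(x$reconstruction$estimate), x$reconstruction$p.value))
  if (!is.null(x$weighted_tests$combined))
    cat(sprintf("  combined within- vs between-year repeatability p = %.3g\n",
                x$weighted_tests$combined$p.value))
  for (n in x$notices) cat("  note:", n, "\n")
  invisible(x)
}

#' Serialize a pipeline report to a JSON-ready list
#'
#' Flattens the fitted objects of a [run_pipeline()] report into plain
#' lists/tables so the result can be written as machine-readable JSON.
#' Deterministic given the report.
#'
#' @param report a `"syndrome_report"`.
#' @return a named list of plain vectors and data frames.
#' @export
report_json <- function(report) {
  meta_tab <- do.call(rbind, lapply(names(report$meta), function(pr) {
    f <- report$meta[[pr]]
    data.frame(pair = pr, k = f$k, pooled_r = f$pooled_r,
               ci_lo = f$ci95_r[1], ci_hi = f$ci95_r[2],
               p = f$p_two_sided, tau2 = f$tau2, Q = f$Q, df = f$df_Q,
               p_Q = f$p_Q, I2 = f$I2, row.names = NULL)
  }))
  ht <- function(h) if (is.null(h)) NULL else
    list(statistic = unname(h$statistic),
         df = if (!is.null(h$parameter)) unname(h$parameter) else NULL,
         p = h$p.value)
  wt <- report$weighted_tests
  list(
    seed = report$seed,
    n_assay_rows = nrow(report$assays),
    effects = as.data.frame(report$effects),
    meta = meta_tab,
    heterogeneity_gate = report$heterogeneity_gate,
    meta_regression = if (is.null(report$meta_regression)) NULL else
      lapply(report$meta_regression, function(m) {
        list(pairwise = lapply(m$pairwise, function(f)
          list(coef = as.list(f$b), se = as.list(f$se), p = as.list(f$pval),
               QM = f$QM, p_QM = f$p_QM, tau2 = f$tau2)),
          multivariate = if (is.null(m$multivariate)) NULL else
            list(coef = as.list(m$multivariate$b),
                 se = as.list(m$multivariate$se),
                 p = as.list(m$multivariate$pval),
                 QM = m$multivariate$QM, p_QM = m$multivariate$p_QM,
                 tau2 = m$multivariate$tau2),
          excluded = m$excluded)
      }),
    repeatability = report$repeatability,
    decomposition = report$decomposition,
    reconstruction = ht(report$reconstruction),
    weighted_tests = if (is.null(wt)) NULL else
      list(one_sample = lapply(wt$one_sample, ht),
           paired = lapply(wt$paired, ht),
           combined = ht(wt$combined)),
    notices = report$notices)
}

.write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_assay_csv(report$assays, file.path(out_dir, "assays.csv"))
  write_effect_tsv(report$effects, file.path(out_dir, "effects.tsv"))
  jsonlite::write_json(report_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
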