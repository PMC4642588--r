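#' Year-level summary statistics from the motivating flycatcher field study
#'
#' Published per-year sample sizes, means and standard errors of the three
#' behavioral traits scored in male collared flycatchers over eight breeding
#' seasons (2007-2015; 2008 was dropped by the field team because fewer than
#' five males were assayed and not all behaviors were screened, and is not
#' included here). Traits: novelty avoidance (latency difference, s),
#' aggression (latency to first attack, s), risk-taking (flight initiation
#' distance, m). Sample sizes differ slightly between traits within a year
#' because a few assays could not score every behavior.
#'
#' These printed numbers are inputs to the package: they calibrate the
#' defaults of [truth_config()] and supply the per-year weights used by the
#' weighted inference helpers.
#'
#' @format A data frame with one row per year and columns
#'   `year`, `n_na`, `mean_na`, `se_na`, `n_ag`, `mean_ag`, `se_ag`,
#'   `n_rt`, `mean_rt`, `se_rt`.
#' @seealso [fly_repeatability] for the repeated-measurement summaries.
#' @export
fly_year_stats <- data.frame(
  year    = c(2007, 2009, 2010, 2011, 2012, 2013, 2014, 2015),
  n_na    = c(21, 33, 28, 40, 17, 44, 45, 40),
  mean_na = c(113.2, 12.5, 108.5, 195.6, 201.1, 138.6, 119.1, 110.6),
  se_na   = c(36.8, 23.1, 27.5, 17.6, 26.9, 22.8, 18.3, 24.1),
  n_ag    = c(23, 34, 31, 54, 25, 56, 53, 46),
  mean_ag = c(50.4, 29.7, 50.3, 55.8, 92.3, 44.5, 40.0, 17.4),
  se_ag   = c(21.8, 12.7, 17.2, 13.9, 24.4, 12.8, 11.7, 7.8),
  n_rt    = c(21, 32, 31, 51, 22, 54, 52, 47),
  mean_rt = c(11.8, 13.0, 14.0, 10.3, 13.5, 9.8, 12.6, 7.5),
  se_rt   = c(1.5, 1.4, 1.2, 0.7, 1.9, 0.8, 1.1, 0.7)
)

#' Within- and between-year repeatabilities from the motivating field study
#'
#' Published repeatability estimates (posterior means with 95% credible
#' intervals) of the three behaviors. Within-year rows are based on males
#' scored at least twice within the same breeding season (five seasons with
#' repeats); the `between` row uses males tested in at least two different
#' seasons, first assay per season only. `n_*` columns count individuals.
#'
#' These printed values are inputs to the sample-size-weighted t tests that
#' ask whether within-year repeatabilities exceed the between-year ones and
#' whether they differ between traits; see [weighted_t_one_sample()] and
#' [weighted_t_paired()].
#'
#' @format A data frame with one row per context (`"2009"`, `"2011"`,
#'   `"2013"`, `"2014"`, `"2015"`, `"between"`) and columns
#'   `context`, `n_na`, `R_na`, `R_na_lo`, `R_na_hi`, `n_ag`, `R_ag`,
#'   `R_ag_lo`, `R_ag_hi`, `n_rt`, `R_rt`, `R_rt_lo`, `R_rt_hi`.
#' @export
fly_repeatability <- data.frame(
  context = c("2009", "2011", "2013", "2014", "2015", "between"),
  n_na    = c(27, 16, 25, 16, 18, 19),
  R_na    = c(0.449, 0.047, 0.235, 0.046, 0.104, 0.021),
  R_na_lo = c(0.003, 0.000, 0.000, 0.000, 0.000, 0.000),
  R_na_hi = c(0.774, 0.482, 0.629, 0.403, 0.525, 0.251),
  n_ag    = c(27, 16, 28, 17, 19, 21),
  R_ag    = c(0.345, 0.037, 0.061, 0.185, 0.147, 0.058),
  R_ag_lo = c(0.032, 0.001, 0.002, 0.002, 0.002, 0.001),
  R_ag_hi = c(0.631, 0.218, 0.232, 0.565, 0.535, 0.314),
  n_rt    = c(26, 16, 28, 17, 19, 21),
  R_rt    = c(0.652, 0.116, 0.414, 0.517, 0.109, 0.117),
  R_rt_lo = c(0.406, 0.011, 0.153, 0.070, 0.006, 0.009),
  R_rt_hi = c(0.837, 0.432, 0.646, 0.820, 0.402, 0.450)
)

# trait keys used across the package; stored orientation: smaller = bolder
.traits <- c("novelty_avoidance_s", "aggression_latency_s", "fid_m")
.trait_pairs <- c("NA-AG", "NA-RT", "AG-RT")

.pair_columns <- function(pair) {
  switch(pair,
    "NA-AG" = .traits[c(1L, 2L)],
    "NA-RT" = .traits[c(1L, 3L)],
    "AG-RT" = .traits[c(2L, 3L)],
    stop("unknown trait pair: ", pair)
  )
}
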