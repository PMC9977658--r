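#' Packaged effective-dose and risk table
#'
#' Per-examination, per-weight-band typical effective doses (mSv) for the
#' 20 commonly performed paediatric general radiography examinations, as
#' established at a major Australian paediatric hospital by Monte Carlo
#' patient dosimetry on weight-matched phantoms. Doses reported only as
#' below 0.001 mSv are stored as 0.001 with `below_threshold = TRUE`. The
#' extra columns `published_one_in_n` and `published_category` carry the
#' institution's published 1-in-N cancer-incidence risk and Calman category
#' for each row; they are reference values for consistency checks, not
#' inputs to any computation.
#'
#' @return A [dose_table()] with 108 (exam, band) rows.
#' @export
rch_dose_table <- function() {
  read_dose_csv(system.file("extdata", "rch_dose_risk.csv",
                            package = "paedradrisk", mustWork = TRUE))
}

#' Packaged weight-banded exposure chart
#'
#' The institutional exposure chart: per view, the kVp range and the
#' recommended mAs for each of the six weight bands (missing cells where a
#' view is only performed on larger children). Grid and source-to-detector
#' metadata are approximate: the chart source marks grid use graphically,
#' which does not survive into this transcription, so `grid` is FALSE
#' throughout and `sid_cm` is 100 except for chest views at 125.
#'
#' @return An [exposure_chart()] with 28 views.
#' @export
rch_exposure_chart <- function() {
  read_chart_csv(system.file("extdata", "rch_exposure_chart.csv",
                             package = "paedradrisk", mustWork = TRUE))
}

#' Packaged examination catalogue
#'
#' The 20 examinations with their ordered view lists and weight-band
#' restrictions (e.g. swimmers views from 26 kg up).
#'
#' @return An [exam_catalogue()].
#' @export
rch_exam_catalogue <- function() {
  read_catalogue_json(system.file("extdata", "rch_exam_catalogue.json",
                                  package = "paedradrisk", mustWork = TRUE))
}

#' Default synthetic growth reference
#'
#' Generated by [make_growth_reference()] under the default configuration.
#' Synthetic: a plausible monotone median weight-for-age table, not fitted
#' to any published reference population. Supply real reference data via
#' [read_growth_csv()] for institutional use.
#'
#' @return A [growth_reference()].
#' @export
synthetic_growth <- function() {
  make_growth_reference(synth_config())
}

#' Default synthetic risk-coefficient table
#'
#' Generated by [make_coefficient_table()] under the default configuration:
#' exponentially age-declining coefficients anchored so the male incidence
#' coefficient at age 5 is 1816 per 100,000 per 0.1 Gy (the published
#' reference value used in the worked example). Synthetic: genuine
#' lifetime-risk tables are user-supplied via [read_coefficients_csv()].
#'
#' @return A [risk_coefficients()] table.
#' @export
synthetic_coefficients <- function() {
  make_coefficient_table(synth_config())
}
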