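#' Build a per-examination, per-band effective dose table
#'
#' Effective doses (mSv) are stored per (examination, weight band), covering
#' all views of the examination together — the conservative maximum for a
#' complete study. Doses typically come from Monte Carlo patient dosimetry
#' on weight-matched phantoms; views the phantoms cannot model (upper
#' extremities) are normalised from published values via
#' [adjust_published_dose()]. Doses reported only as "below 0.001 mSv" are
#' stored as the bound 0.001 with `below_threshold = TRUE`, and any risk
#' derived from them is an upper bound.
#'
#' @param data Data frame with columns `exam`, `band` (band label),
#'   `effective_dose_mSv`, and optionally `provenance` (one of
#'   `"monte_carlo"`, `"normalised_published"`, `"user_supplied"`),
#'   `below_threshold` (logical) and any extra columns (kept).
#' @return A `dose_table` data frame.
#' @seealso [exam_dose()], [read_dose_csv()], [rch_dose_table()]
#' @export
dose_table <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("exam", "band", "effective_dose_mSv")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    pr_stop(paste("dose table missing columns:",
                  paste(missing_cols, collapse = ", ")),
            "paedradrisk_invalid_argument")
  }
  out <- as.data.frame(data)
  out$exam <- as.character(out$exam)
  out$band <- as.character(out$band)
  out$effective_dose_mSv <- as.numeric(out$effective_dose_mSv)
  if (!"provenance" %in% names(out)) {
    out$provenance <- rep("user_supplied", nrow(out))
  }
  if (!"below_threshold" %in% names(out)) {
    out$below_threshold <- rep(FALSE, nrow(out))
  }
  out$below_threshold <- as.logical(out$below_threshold)
  bad_prov <- setdiff(unique(out$provenance),
                      c("monte_carlo", "normalised_published", "user_supplied"))
  if (length(bad_prov)) {
    pr_stop(paste("unknown provenance:", paste(bad_prov, collapse = ", ")),
            "paedradrisk_invalid_argument")
  }
  if (any(!is.finite(out$effective_dose_mSv) | out$effective_dose_mSv < 0)) {
    pr_stop("effective doses must be non-negative", "paedradrisk_invalid_argument")
  }
  for (b in unique(out$band)) as_weight_band(b) # validates labels
  if (anyDuplicated(out[c("exam", "band")])) {
    pr_stop("duplicate (exam, band) dose records", "paedradrisk_invalid_argument")
  }
  class(out) <- c("dose_table", "data.frame")
  out
}

#' Normalise a published effective dose to local exposure parameters
#'
#' Effective dose scales linearly with the tube current-time product (mAs)
#' and approximately with the square of tube voltage (kVp). A published dose
#' measured at one set of parameters is rescaled to local parameters as
#' `dose x (mas_local / mas_pub) x (kvp_local / kvp_pub)^2`. The rule
#' corrects beam quantity only; differences in filtration and geometry are
#' not accounted for.
#'
#' @param dose_pub Published effective dose (mSv).
#' @param kvp_pub,mas_pub Tube parameters the published dose was measured at.
#' @param kvp_local,mas_local Local tube parameters.
#' @return Normalised effective dose in mSv.
#' @examples
#' adjust_published_dose(0.010, kvp_pub = 50, mas_pub = 1,
#'                       kvp_local = 55, mas_local = 1) # 0.0121
#' @export
adjust_published_dose <- function(dose_pub, kvp_pub, mas_pub,
                                  kvp_local, mas_local) {
  pr_check_positive(dose_pub, "dose_pub")
  pr_check_positive(kvp_pub, "kvp_pub")
  pr_check_positive(mas_pub, "mas_pub")
  pr_check_positive(kvp_local, "kvp_local")
  pr_check_positive(mas_local, "mas_local")
  dose_pub * (mas_local / mas_pub) * (kvp_local / kvp_pub)^2
}

#' Effective dose for an examination in a weight band
#'
#' @param doses A [dose_table()].
#' @param exam_name Examination name.
#' @param band A `weight_band`, band label or index.
#' @return Effective dose in mSv, with attribute `below_threshold` set when
#'   the stored value is an upper bound.
#' @examples
#' exam_dose(rch_dose_table(), "Chest AP", "60+") # 0.033 mSv
#' @export
exam_dose <- function(doses, exam_name, band) {
  stopifnot(inherits(doses, "dose_table"))
  band <- as_weight_band(band)
  rows <- doses[doses$exam == exam_name, ]
  if (nrow(rows) == 0) {
    pr_stop(sprintf("no dose records for examination '%s'", exam_name),
            "paedradrisk_lookup_error")
  }
  i <- match(band$label, rows$band)
  if (is.na(i)) {
    pr_stop(sprintf(
      "examination '%s' has no dose for weight band %s; it is only performed in bands %s",
      exam_name, band$label, paste(sort(rows$band), collapse = ", ")),
      "paedradrisk_band_restricted")
  }
  structure(rows$effective_dose_mSv[i],
            below_threshold = isTRUE(rows$below_threshold[i]))
}

#' Sum per-view effective doses into an examination dose
#'
#' Effective dose is additive over the views of a study.
#'
#' @param per_view Numeric vector of non-negative per-view doses (mSv).
#' @return Total effective dose in mSv.
#' @export
sum_view_doses <- function(per_view) {
  if (!is.numeric(per_view) || length(per_view) == 0) {
    pr_stop("`per_view` must be a non-empty numeric vector",
            "paedradrisk_invalid_argument")
  }
  if (any(!is.finite(per_view) | per_view < 0)) {
    pr_stop("per-view doses must be finite and non-negative",
            "paedradrisk_invalid_argument")
  }
  sum(per_view)
}

#' Read a dose table from CSV
#'
#' Expected columns: `exam,band,effective_dose_mSv,provenance,below_threshold`
#' (band labels as in [weight_bands()]); extra columns are kept.
#'
#' @param path Path to a CSV file.
#' @return A [dose_table()].
#' @export
read_dose_csv <- function(path) {
  dose_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Read published dose references from CSV
#'
#' Expected columns: `view,effective_dose_mSv,kvp_pub,mas_pub` — published
#' per-view doses with the tube parameters they were measured at, ready for
#' [adjust_published_dose()].
#'
#' @param path Path to a CSV file.
#' @return A data frame of published dose references.
#' @export
read_published_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("view", "effective_dose_mSv", "kvp_pub", "mas_pub")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    pr_stop(paste("published-dose table missing columns:",
                  paste(missing_cols, collapse = ", ")),
            "paedradrisk_invalid_argument")
  }
  if (any(df$effective_dose_mSv <= 0 | df$kvp_pub <= 0 | df$mas_pub <= 0)) {
    pr_stop("published doses and parameters must be positive",
            "paedradrisk_invalid_argument")
  }
  df
}
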