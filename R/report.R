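#' Risk summary for an individual patient and examination
#'
#' Resolves the patient's weight band from the growth reference, looks up
#' the examination's effective dose for that band (or takes an explicit
#' dose), evaluates the excess cancer risk at the patient's own age and sex
#' — not the band-conservative maximum, which is reserved for institutional
#' reporting ([risk_report()]) — and returns the full communication summary.
#'
#' @param exam_name Examination name (see [rch_exam_catalogue()]).
#' @param age_years Integer age, 0-18.
#' @param sex `"F"` or `"M"` (full words accepted).
#' @param dose_mSv Optional effective dose override in mSv; when NULL the
#'   packaged/given dose table supplies it.
#' @param growth A [growth_reference()]; defaults to [synthetic_growth()].
#' @param doses A [dose_table()]; defaults to [rch_dose_table()].
#' @param coeffs A [risk_coefficients()] table; defaults to
#'   [synthetic_coefficients()] (supply real tables for clinical use).
#' @param catalogue An [exam_catalogue()] used to enforce band
#'   restrictions; defaults to [rch_exam_catalogue()]. Set NULL to skip.
#' @param endpoint `"incidence"` (default) or `"mortality"`.
#' @return A `patient_risk` object: a [communication_summary()] plus the
#'   resolved `weight_kg` and `band`.
#' @examples
#' coeffs <- synthetic_coefficients()
#' patient_risk("Chest AP", age_years = 5, sex = "M", dose_mSv = 1,
#'              coeffs = coeffs)
#' @export
patient_risk <- function(exam_name, age_years, sex, dose_mSv = NULL,
                         growth = synthetic_growth(),
                         doses = rch_dose_table(),
                         coeffs = synthetic_coefficients(),
                         catalogue = rch_exam_catalogue(),
                         endpoint = "incidence") {
  if (!is.numeric(age_years) || length(age_years) != 1L ||
      age_years < 0 || age_years > 18 || age_years != round(age_years)) {
    pr_stop("`age_years` must be an integer between 0 and 18",
            "paedradrisk_invalid_argument")
  }
  sex <- pr_sex(sex)
  weight <- median_weight(growth, age_years, sex)
  band <- band_for_weight(weight)
  if (!is.null(catalogue) && exam_name %in% names(catalogue$exams)) {
    allowed <- exam_bands(catalogue, exam_name)
    if (!band$index %in% allowed) {
      pr_stop(sprintf(
        "examination '%s' is not performed in weight band %s (age %d, %.1f kg); valid bands: %s",
        exam_name, band$label, age_years, weight,
        paste(weight_bands()$label[allowed + 1L], collapse = ", ")),
        "paedradrisk_band_restricted")
    }
  }
  below <- FALSE
  if (is.null(dose_mSv)) {
    d <- exam_dose(doses, exam_name, band)
    below <- isTRUE(attr(d, "below_threshold"))
    dose_mSv <- as.numeric(d)
  } else {
    pr_check_nonnegative(dose_mSv, "dose_mSv")
  }
  coeff <- interpolate_coefficient(coeffs, age_years, sex, endpoint)
  est <- new_risk_estimate(
    excess_per_100k = risk_from_dose(dose_mSv, coeff),
    effective_dose_mSv = dose_mSv, age_years = age_years, sex = sex,
    endpoint = endpoint, exam = exam_name, band = band$label,
    below_threshold = below
  )
  out <- communication_summary(est)
  out$weight_kg <- weight
  out$band <- band
  class(out) <- c("patient_risk", class(out))
  out
}

#' @export
print.patient_risk <- function(x, ...) {
  cat(sprintf("Examination:           %s\n", x$risk$exam))
  cat(sprintf("Patient:               age %d, sex %s, median weight %.1f kg (band %s)\n",
              x$risk$age_years, x$risk$sex, x$weight_kg, x$band$label))
  NextMethod()
}

#' Institutional per-examination, per-band risk report
#'
#' One row per (examination, weight band) dose record, carrying the typical
#' effective dose, the band-conservative maximum excess risk
#' ([band_max_risk()]), its 1-in-N form and Calman category, BERT and
#' flight-time equivalents — both as unrounded numerics and as display
#' strings. With `merge_bands = TRUE`, adjacent bands of an examination
#' whose formatted outputs are identical are collapsed into one row with a
#' combined band label.
#'
#' @param doses A [dose_table()]; defaults to [rch_dose_table()].
#' @param growth A [growth_reference()]; defaults to [synthetic_growth()].
#' @param coeffs A [risk_coefficients()] table; defaults to
#'   [synthetic_coefficients()].
#' @param endpoint `"incidence"` (default) or `"mortality"`.
#' @param merge_bands Collapse adjacent bands with identical displays.
#' @return A `risk_report` data frame.
#' @export
risk_report <- function(doses = rch_dose_table(),
                        growth = synthetic_growth(),
                        coeffs = synthetic_coefficients(),
                        endpoint = "incidence",
                        merge_bands = FALSE) {
  stopifnot(inherits(doses, "dose_table"))
  if (nrow(doses) == 0) {
    pr_stop("dose table is empty; nothing to report",
            "paedradrisk_invalid_argument")
  }
  band_order <- weight_bands()$label
  rows <- lapply(seq_len(nrow(doses)), function(i) {
    est <- band_max_risk(doses$exam[i], doses$band[i], growth, doses, coeffs,
                         endpoint)
    cs <- communication_summary(est)
    d <- cs$display
    data.frame(
      exam = doses$exam[i], band = doses$band[i],
      effective_dose_mSv = est$effective_dose_mSv,
      below_threshold = est$below_threshold,
      risk_per_100k = est$excess_per_100k,
      one_in_n = est$one_in_n,
      category = cs$category,
      max_age_years = est$age_years, max_sex = est$sex,
      bert_days = cs$bert_days, flight_hours = cs$flight_hours,
      dose_display = d[["dose"]], risk_display = d[["risk_per_100k"]],
      one_in_n_display = d[["one_in_n_table"]],
      bert_display = d[["bert"]], flight_display = d[["flight"]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$exam, unique(doses$exam)),
                   match(out$band, band_order)), ]
  rownames(out) <- NULL
  if (merge_bands) out <- merge_report_bands(out)
  class(out) <- c("risk_report", "data.frame")
  attr(out, "endpoint") <- endpoint
  out
}

# collapse runs of adjacent bands (within an exam) whose formatted outputs
# coincide; the combined label spans the run, e.g. "3-15"
merge_report_bands <- function(report) {
  key <- paste(report$dose_display, report$one_in_n_display,
               report$category, report$bert_display, report$flight_display)
  keep <- logical(nrow(report))
  labels <- report$band
  i <- 1L
  while (i <= nrow(report)) {
    j <- i
    while (j < nrow(report) && report$exam[j + 1L] == report$exam[i] &&
           key[j + 1L] == key[i]) j <- j + 1L
    keep[i] <- TRUE
    if (j > i) {
      first <- report$band[i]
      last <- report$band[j]
      lower <- sub("-.*$", "", sub("\\+$", "", first))
      labels[i] <- if (grepl("\\+$", last)) paste0(lower, "+") else
        paste0(lower, "-", sub("^.*-", "", last))
    }
    i <- j + 1L
  }
  out <- report[keep, ]
  out$band <- labels[keep]
  rownames(out) <- NULL
  out
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("Radiography risk report (%s, %d rows)\n",
              attr(x, "endpoint"), nrow(x)))
  show <- x[c("exam", "band", "dose_display", "one_in_n_display",
              "category", "bert_display")]
  names(show) <- c("exam", "band", "dose_mSv", "risk_1_in", "category", "BERT")
  print.data.frame(utils::head(show, 20), right = FALSE)
  if (nrow(x) > 20) cat(sprintf("... and %d more rows\n", nrow(x) - 20))
  invisible(x)
}

#' Write a risk report to CSV or JSON
#'
#' CSV keeps unrounded numeric columns alongside the display columns; JSON
#' nests each row with both.
#'
#' @param report A [risk_report()].
#' @param path Output path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  stopifnot(inherits(report, "risk_report"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    jsonlite::write_json(as.data.frame(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}
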