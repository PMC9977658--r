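#' Build a lifetime risk-coefficient table
#'
#' Lifetime-attributable-risk coefficients give the expected number of
#' excess cancer cases (or deaths) per 100,000 persons exposed to a single
#' 0.1 Gy (100 mSv) dose, tabulated on a sparse grid of ages at exposure,
#' separately by sex and endpoint. Coefficients at in-between ages are
#' obtained by linear interpolation ([interpolate_coefficient()]).
#'
#' @param data Data frame with columns `age_years`, `sex` (`"F"`/`"M"`),
#'   `endpoint` (`"incidence"`/`"mortality"`) and `excess_per_100k_per_0.1Gy`
#'   (alias `excess_per_100k` accepted).
#' @return A `risk_coefficients` data frame. Within each (sex, endpoint)
#'   stratum the age grid must be strictly increasing and all coefficients
#'   positive.
#' @seealso [interpolate_coefficient()], [make_coefficient_table()]
#' @export
risk_coefficients <- function(data) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data)
  val_col <- intersect(c("excess_per_100k_per_0.1Gy", "excess_per_100k"),
                       names(data))
  if (length(val_col) == 0) {
    pr_stop("coefficient table needs an excess_per_100k_per_0.1Gy column",
            "paedradrisk_invalid_argument")
  }
  out <- data.frame(
    age_years = as.numeric(data$age_years),
    sex = pr_sex(data$sex),
    endpoint = as.character(data$endpoint),
    excess_per_100k = as.numeric(data[[val_col[1]]]),
    stringsAsFactors = FALSE
  )
  if (!all(out$endpoint %in% c("incidence", "mortality"))) {
    pr_stop("endpoint must be 'incidence' or 'mortality'",
            "paedradrisk_invalid_argument")
  }
  if (any(!is.finite(out$excess_per_100k) | out$excess_per_100k <= 0)) {
    pr_stop("all risk coefficients must be positive",
            "paedradrisk_invalid_argument")
  }
  # strictly increasing grid per stratum == no duplicated ages once sorted
  if (anyDuplicated(out[c("age_years", "sex", "endpoint")])) {
    pr_stop("age grid must be strictly increasing within each (sex, endpoint)",
            "paedradrisk_invalid_argument")
  }
  class(out) <- c("risk_coefficients", "data.frame")
  out
}

#' Interpolate a risk coefficient at an age
#'
#' Returns the tabulated excess-cases-per-100,000-per-0.1-Gy coefficient at
#' grid ages, and the linear interpolation between the bracketing grid ages
#' otherwise. Ages outside the grid are clamped to the nearest grid age
#' with a warning (the tables define risk only between their endpoints).
#'
#' @param coeffs A [risk_coefficients()] table.
#' @param age_years Age at exposure in years (may be fractional).
#' @param sex `"F"` or `"M"`.
#' @param endpoint `"incidence"` (default) or `"mortality"`.
#' @return Excess cases per 100,000 per 0.1 Gy.
#' @export
interpolate_coefficient <- function(coeffs, age_years, sex,
                                    endpoint = "incidence") {
  stopifnot(inherits(coeffs, "risk_coefficients"))
  sex <- pr_sex(sex)
  sub <- coeffs[coeffs$sex == sex & coeffs$endpoint == endpoint, ]
  if (nrow(sub) == 0) {
    pr_stop(sprintf("no coefficients for sex %s, endpoint %s", sex, endpoint),
            "paedradrisk_lookup_error")
  }
  sub <- sub[order(sub$age_years), ]
  if (age_years < min(sub$age_years) || age_years > max(sub$age_years)) {
    warning(sprintf(
      "age %.3g outside coefficient grid [%g, %g]; clamped to nearest grid age",
      age_years, min(sub$age_years), max(sub$age_years)))
    age_years <- min(max(age_years, min(sub$age_years)), max(sub$age_years))
  }
  if (nrow(sub) == 1L) return(sub$excess_per_100k)
  stats::approx(sub$age_years, sub$excess_per_100k, xout = age_years,
                method = "linear", ties = "ordered")$y
}

#' Scale a risk coefficient to an effective dose
#'
#' Under the linear no-threshold assumption, the excess risk from a dose E
#' is the per-0.1-Gy (100 mSv) coefficient scaled by E/100:
#' `excess_per_100k = (dose_mSv / 100) x coefficient`. The value is kept
#' unrounded; rounding is a display concern ([format_summary()]).
#'
#' @param effective_dose_mSv Effective dose in mSv (non-negative).
#' @param coefficient Excess cases per 100,000 per 0.1 Gy.
#' @return Unrounded excess cases per 100,000.
#' @examples
#' risk_from_dose(1, 1816) # 18.16, displayed as 18.2
#' @export
risk_from_dose <- function(effective_dose_mSv, coefficient) {
  pr_check_nonnegative(effective_dose_mSv, "effective_dose_mSv")
  pr_check_positive(coefficient, "coefficient")
  (effective_dose_mSv / 100) * coefficient
}

#' Express a per-100,000 excess risk as "1 in N"
#'
#' N is computed from the unrounded risk (`100000 / excess_per_100k`), so a
#' displayed risk of 18.2 per 100,000 still yields N = 5507, not 5495.
#'
#' @param excess_per_100k Excess cases per 100,000 (non-negative).
#' @return N as a positive real; `Inf` for zero risk.
#' @examples
#' one_in_n(18.16) # 5506.608
#' @export
one_in_n <- function(excess_per_100k) {
  pr_check_nonnegative(excess_per_100k, "excess_per_100k")
  if (excess_per_100k == 0) return(Inf)
  1e5 / excess_per_100k
}

new_risk_estimate <- function(excess_per_100k, effective_dose_mSv, age_years,
                              sex, endpoint, exam = NA_character_,
                              band = NA_character_, below_threshold = FALSE) {
  structure(
    list(excess_per_100k = excess_per_100k,
         one_in_n = one_in_n(excess_per_100k),
         effective_dose_mSv = effective_dose_mSv,
         age_years = age_years, sex = sex, endpoint = endpoint,
         exam = exam, band = band, below_threshold = below_threshold),
    class = "risk_estimate"
  )
}

#' @export
print.risk_estimate <- function(x, ...) {
  lt <- if (isTRUE(x$below_threshold)) "less than " else ""
  cat(sprintf("<risk estimate: %s%s excess %s per 100,000 (1 in %s)>\n",
              lt, formatC(round(x$excess_per_100k, 1), format = "fg"),
              x$endpoint, format(round(x$one_in_n))))
  cat(sprintf("  dose %s mSv, age %s, sex %s\n",
              format(x$effective_dose_mSv), format(x$age_years), x$sex))
  invisible(x)
}

#' Conservative maximum risk for an examination in a weight band
#'
#' Every (age, sex) whose median weight falls in the band is evaluated with
#' the band's examination dose, and the estimate with the largest excess
#' risk represents the band. Ties break deterministically to the lowest
#' age, then female before male. The returned estimate records which
#' (age, sex) attained the maximum.
#'
#' @param exam_name Examination name (must exist in `doses`).
#' @param band A `weight_band`, band label or index.
#' @param growth A [growth_reference()].
#' @param doses A [dose_table()].
#' @param coeffs A [risk_coefficients()] table.
#' @param endpoint `"incidence"` (default) or `"mortality"`.
#' @return A `risk_estimate`.
#' @export
band_max_risk <- function(exam_name, band, growth, doses, coeffs,
                          endpoint = "incidence") {
  band <- as_weight_band(band)
  members <- ages_in_band(growth, band)
  if (nrow(members) == 0) {
    pr_stop(sprintf(
      "no (age, sex) in the growth reference has median weight in band %s; no representative age",
      band$label), "paedradrisk_no_representative_age")
  }
  dose <- exam_dose(doses, exam_name, band)
  # deterministic tie-break: ascending age, female before male
  members <- members[order(members$age_years, members$sex), ]
  risks <- vapply(seq_len(nrow(members)), function(i) {
    coeff <- interpolate_coefficient(coeffs, members$age_years[i],
                                     members$sex[i], endpoint)
    risk_from_dose(as.numeric(dose), coeff)
  }, numeric(1))
  k <- which.max(risks)
  new_risk_estimate(
    excess_per_100k = risks[k],
    effective_dose_mSv = as.numeric(dose),
    age_years = members$age_years[k], sex = members$sex[k],
    endpoint = endpoint, exam = exam_name, band = band$label,
    below_threshold = isTRUE(attr(dose, "below_threshold"))
  )
}

#' Read a risk-coefficient table from CSV
#'
#' Expected columns: `age_years,sex,endpoint,excess_per_100k_per_0.1Gy`.
#'
#' @param path Path to a CSV file.
#' @return A [risk_coefficients()] table.
#' @export
read_coefficients_csv <- function(path) {
  risk_coefficients(utils::read.csv(path, stringsAsFactors = FALSE,
                                    check.names = FALSE))
}

#' Write a risk-coefficient table to CSV
#'
#' @param coeffs A [risk_coefficients()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficients_csv <- function(coeffs, path) {
  stopifnot(inherits(coeffs, "risk_coefficients"))
  out <- as.data.frame(coeffs)
  names(out)[names(out) == "excess_per_100k"] <- "excess_per_100k_per_0.1Gy"
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
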