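#' Calman risk classification table
#'
#' Six verbal risk levels keyed to order-of-magnitude probability bands,
#' from Negligible (below 1 in 1,000,000) to High (more than 1 in 100).
#' The published ranges share their boundaries; this implementation makes
#' the bins disjoint by taking each bin's lower probability bound as
#' inclusive and its upper bound as exclusive, so e.g. a probability of
#' exactly 1/1000 classifies as Moderate.
#'
#' @return A data frame with columns `category`, `p_lower`, `p_upper`
#'   (probability bounds) ordered from least to most severe.
#' @export
calman_table <- function() {
  data.frame(
    category = c("Negligible", "Minimal", "Very Low", "Low", "Moderate", "High"),
    p_lower = c(0, 1e-6, 1e-5, 1e-4, 1e-3, 1e-2),
    p_upper = c(1e-6, 1e-5, 1e-4, 1e-3, 1e-2, 1),
    stringsAsFactors = FALSE
  )
}

#' Classify a risk probability on the Calman scale
#'
#' @param probability Risk probability in (0, 1].
#' @return Category name; one of Negligible, Minimal, Very Low, Low,
#'   Moderate, High.
#' @examples
#' classify_calman(1 / 283000) # "Minimal"
#' classify_calman(1 / 5507)   # "Low"
#' @export
classify_calman <- function(probability) {
  if (!is.numeric(probability) || any(!is.finite(probability)) ||
      any(probability <= 0) || any(probability > 1)) {
    pr_stop("`probability` must lie in (0, 1]", "paedradrisk_invalid_argument")
  }
  tab <- calman_table()
  # lower bound inclusive, upper exclusive; top bin [1e-2, 1] closed above
  idx <- findInterval(probability, tab$p_lower, left.open = FALSE)
  tab$category[idx]
}

#' Background equivalent radiation time (BERT)
#'
#' The duration of natural background exposure delivering the same
#' effective dose, using the Australian background rate of 1.5 mSv per
#' annum: `BERT = dose / 1.5` years.
#'
#' @param effective_dose_mSv Effective dose in mSv (non-negative).
#' @return BERT in years.
#' @seealso [bert_display()] for the hours/days/months rendering.
#' @export
bert <- function(effective_dose_mSv) {
  check_dose_vector(effective_dose_mSv)
  effective_dose_mSv / 1.5
}

# doses may come vectorised (whole report columns); all must be finite, >= 0
check_dose_vector <- function(x) {
  if (!is.numeric(x) || length(x) == 0 || any(!is.finite(x)) || any(x < 0)) {
    pr_stop("`effective_dose_mSv` must be a single finite non-negative number (or vector thereof)",
            "paedradrisk_invalid_argument")
  }
  invisible(x)
}

#' BERT rendered in a human-scale unit
#'
#' Converts [bert()] years to hours, days or months as appropriate:
#' under 2 days it is shown in hours, under 3 months in days, otherwise in
#' months. A year is 365.25 days; a month is a twelfth of that.
#'
#' @param effective_dose_mSv Effective dose in mSv.
#' @return A display string such as `"8.0 days"`.
#' @examples
#' bert_display(0.033) # "8.0 days"
#' @export
bert_display <- function(effective_dose_mSv) {
  years <- bert(effective_dose_mSv)
  days <- years * 365.25
  if (days < 2) {
    sprintf("%.1f hours", days * 24)
  } else if (days < 3 * 365.25 / 12) {
    sprintf("%.1f days", days)
  } else {
    sprintf("%.1f months", days / (365.25 / 12))
  }
}

#' International flight-time equivalent of a dose
#'
#' Long-haul flying incurs about 0.00239 mSv of cosmic-ray dose per hour
#' (a 0.11 mSv Melbourne-London return flight over 46 hours), so
#' `hours = dose / 0.00239`.
#'
#' @param effective_dose_mSv Effective dose in mSv (non-negative).
#' @return Equivalent flight time in hours.
#' @examples
#' flight_hours(0.11) # about 46 hours
#' @export
flight_hours <- function(effective_dose_mSv) {
  check_dose_vector(effective_dose_mSv)
  effective_dose_mSv / 0.00239
}

#' Cumulative risk over repeated examinations
#'
#' Stochastic radiation risks add over a person's lifetime: each
#' examination's risk is unchanged by the others, and the combined excess
#' risk is the sum. All estimates must share an endpoint.
#'
#' @param estimates A list of `risk_estimate` objects (see
#'   [band_max_risk()]), or a single estimate.
#' @return A `risk_estimate` for the summed risk, re-classified on the
#'   Calman scale via the summed probability; `age_years` and `sex` are NA
#'   unless shared by every component.
#' @export
cumulative_risk <- function(estimates) {
  if (inherits(estimates, "risk_estimate")) estimates <- list(estimates)
  if (!is.list(estimates) || length(estimates) == 0 ||
      !all(vapply(estimates, inherits, logical(1), "risk_estimate"))) {
    pr_stop("`estimates` must be a non-empty list of risk_estimate objects",
            "paedradrisk_invalid_argument")
  }
  eps <- unique(vapply(estimates, function(e) e$endpoint, character(1)))
  if (length(eps) != 1L) {
    pr_stop("cumulative risk requires a single endpoint; got mixed endpoints",
            "paedradrisk_invalid_argument")
  }
  total <- sum(vapply(estimates, function(e) e$excess_per_100k, numeric(1)))
  dose <- sum(vapply(estimates, function(e) e$effective_dose_mSv, numeric(1)))
  uniq <- function(f) {
    v <- unique(vapply(estimates, f, vector(mode = "numeric", length = 1)))
    if (length(v) == 1L) v else NA_real_
  }
  sexes <- unique(vapply(estimates, function(e) e$sex, character(1)))
  new_risk_estimate(
    excess_per_100k = total, effective_dose_mSv = dose,
    age_years = uniq(function(e) as.numeric(e$age_years)),
    sex = if (length(sexes) == 1L) sexes else NA_character_,
    endpoint = eps,
    below_threshold = any(vapply(estimates, function(e)
      isTRUE(e$below_threshold), logical(1)))
  )
}

#' Calman category of a risk estimate
#'
#' @param estimate A `risk_estimate`.
#' @return Category name.
#' @export
risk_category <- function(estimate) {
  stopifnot(inherits(estimate, "risk_estimate"))
  classify_calman(estimate$excess_per_100k / 1e5)
}

#' Format a "1 in N" denominator
#'
#' Table style rounds N to the nearest 100 below 10,000 and to three
#' significant figures at or above (matching e.g. 9400 and 166,000);
#' running-text style rounds to the nearest integer (e.g. 5507).
#'
#' @param n The denominator (positive real, possibly `Inf`).
#' @param style `"table"` or `"text"`.
#' @return A display string with thousands separators.
#' @export
format_one_in_n <- function(n, style = c("table", "text")) {
  style <- match.arg(style)
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n <= 0) {
    pr_stop("`n` must be a single positive number", "paedradrisk_invalid_argument")
  }
  if (!is.finite(n)) return("-")
  if (style == "text") {
    # running-text form, no separators: "1 in 5507"
    return(format(round(n), scientific = FALSE, trim = TRUE))
  }
  # below 10,000: nearest hundred, no separator (9400); above: 3 significant
  # figures with thousands separators (166,000)
  if (n < 1e4) {
    format(round(n / 100) * 100, scientific = FALSE, trim = TRUE)
  } else {
    format(signif(n, 3), big.mark = ",", scientific = FALSE, trim = TRUE)
  }
}

format_dose <- function(dose_mSv, below_threshold = FALSE) {
  if (below_threshold || dose_mSv < 0.001) "<0.001" else sprintf("%.3f", dose_mSv)
}

#' Full communication summary for a risk estimate
#'
#' Bundles the quantitative estimate with every communication form: Calman
#' category, BERT, flight-time equivalent and deterministic display strings.
#'
#' @param estimate A `risk_estimate`.
#' @return A `communication_summary` list with elements
#'   `effective_dose_mSv`, `risk` (the estimate), `category`, `bert_years`,
#'   `bert_days`, `flight_hours` and `display` (named character vector).
#' @export
communication_summary <- function(estimate) {
  stopifnot(inherits(estimate, "risk_estimate"))
  dose <- estimate$effective_dose_mSv
  category <- risk_category(estimate)
  p <- estimate$excess_per_100k / 1e5
  lt <- if (isTRUE(estimate$below_threshold)) "less than " else ""
  display <- c(
    dose = format_dose(dose, isTRUE(estimate$below_threshold)),
    risk_per_100k = paste0(lt, sprintf("%.1f", round(estimate$excess_per_100k, 1)),
                           " per 100,000"),
    percent = paste0(lt, formatC(signif(p * 100, 3), format = "fg"), "%"),
    one_in_n_text = paste("1 in", format_one_in_n(estimate$one_in_n, "text")),
    one_in_n_table = format_one_in_n(estimate$one_in_n, "table"),
    category = category,
    bert = bert_display(dose),
    flight = sprintf("%.1f hours", flight_hours(dose))
  )
  structure(
    list(effective_dose_mSv = dose, risk = estimate, category = category,
         bert_years = bert(dose), bert_days = bert(dose) * 365.25,
         flight_hours = flight_hours(dose), display = display),
    class = "communication_summary"
  )
}

#' Display strings of a communication summary
#'
#' @param summary A [communication_summary()].
#' @return Named character vector of deterministic display strings.
#' @export
format_summary <- function(summary) {
  stopifnot(inherits(summary, "communication_summary"))
  summary$display
}

#' @export
print.communication_summary <- function(x, ...) {
  d <- x$display
  cat(sprintf("Effective dose:        %s mSv\n", d[["dose"]]))
  cat(sprintf("Excess %s risk: %s (%s; %s)\n", x$risk$endpoint,
              d[["risk_per_100k"]], d[["one_in_n_text"]], d[["percent"]]))
  cat(sprintf("Risk category:         %s\n", d[["category"]]))
  cat(sprintf("Background equivalent: %s\n", d[["bert"]]))
  cat(sprintf("Flight equivalent:     %s\n", d[["flight"]]))
  invisible(x)
}
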