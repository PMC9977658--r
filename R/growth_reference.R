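#' Build a median growth reference table
#'
#' A growth reference holds sex-specific median body weight at each integer
#' age 0-18 years. Weight may be given directly, or — mirroring published
#' reference data where weight-for-age stops at age 10 — derived for older
#' ages from median BMI and height via `weight = BMI x height^2`.
#'
#' @param data A data frame with columns `age_years` (integers 0-18),
#'   `sex` (`"F"`/`"M"`, full words accepted), and either `weight_kg` or
#'   both `bmi` and `height_m` per row. Optional columns may be `NA` where
#'   unused.
#' @return A `growth_reference` data frame with a computed `weight_kg`
#'   column for every row. Median weight must be non-decreasing in age
#'   within each sex; violations are an error.
#' @seealso [median_weight()], [ages_in_band()], [read_growth_csv()]
#' @export
growth_reference <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("age_years", "sex")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    pr_stop(paste("growth data missing columns:",
                  paste(missing_cols, collapse = ", ")),
            "paedradrisk_invalid_argument")
  }
  out <- data.frame(
    age_years = as.integer(data$age_years),
    sex = pr_sex(data$sex),
    stringsAsFactors = FALSE
  )
  if (any(out$age_years < 0 | out$age_years > 18)) {
    pr_stop("growth reference ages must lie in 0-18 years",
            "paedradrisk_invalid_argument")
  }
  w <- if ("weight_kg" %in% names(data)) as.numeric(data$weight_kg) else
    rep(NA_real_, nrow(data))
  bmi <- if ("bmi" %in% names(data)) as.numeric(data$bmi) else
    rep(NA_real_, nrow(data))
  h <- if ("height_m" %in% names(data)) as.numeric(data$height_m) else
    rep(NA_real_, nrow(data))
  derive <- is.na(w)
  if (any(derive & (is.na(bmi) | is.na(h)))) {
    pr_stop("rows without weight_kg need both bmi and height_m",
            "paedradrisk_invalid_argument")
  }
  if (any(derive)) {
    w[derive] <- mapply(weight_from_bmi_height, bmi[derive], h[derive])
  }
  if (any(!is.finite(w) | w <= 0)) {
    pr_stop("all median weights must be positive", "paedradrisk_invalid_argument")
  }
  # direct weight alongside bmi+height must be self-consistent (2% slack)
  both <- !derive & !is.na(bmi) & !is.na(h)
  if (any(both)) {
    rel <- abs(w[both] - bmi[both] * h[both]^2) / w[both]
    if (any(rel >= 0.02)) {
      pr_stop("weight_kg inconsistent with bmi x height_m^2 (>= 2% off)",
              "paedradrisk_invalid_argument")
    }
  }
  out$weight_kg <- w
  out$height_m <- h
  out$bmi <- bmi
  if (anyDuplicated(out[c("age_years", "sex")])) {
    pr_stop("duplicate (age, sex) rows in growth reference",
            "paedradrisk_invalid_argument")
  }
  for (s in unique(out$sex)) {
    rows <- out[out$sex == s, ]
    rows <- rows[order(rows$age_years), ]
    if (is.unsorted(rows$weight_kg)) {
      pr_stop(sprintf("median weight must be non-decreasing in age (sex %s)", s),
              "paedradrisk_invalid_argument")
    }
  }
  class(out) <- c("growth_reference", "data.frame")
  out
}

#' Derive body weight from BMI and height
#'
#' The defining identity of the body-mass index: `weight = BMI x height^2`.
#'
#' @param bmi Body-mass index in kg/m^2.
#' @param height_m Height in metres.
#' @return Weight in kilograms.
#' @examples
#' weight_from_bmi_height(21.31, 1.631) # 56.69 kg
#' @export
weight_from_bmi_height <- function(bmi, height_m) {
  pr_check_positive(bmi, "bmi")
  pr_check_positive(height_m, "height_m")
  bmi * height_m^2
}

#' Median weight for an age and sex
#'
#' @param growth A [growth_reference()].
#' @param age_years Integer age 0-18.
#' @param sex `"F"` or `"M"` (full words accepted).
#' @return Median weight in kilograms.
#' @export
median_weight <- function(growth, age_years, sex) {
  stopifnot(inherits(growth, "growth_reference"))
  sex <- pr_sex(sex)
  i <- which(growth$age_years == age_years & growth$sex == sex)
  if (length(i) != 1L) {
    pr_stop(sprintf("no growth record for age %s, sex %s", age_years, sex),
            "paedradrisk_lookup_error")
  }
  growth$weight_kg[i]
}

#' Ages whose median weight falls in a weight band
#'
#' Enumerates every (age, sex) combination in the growth reference whose
#' median weight maps into the given band. Used for the conservative
#' per-band maximum-risk aggregation: each band is represented by the
#' member ages at greatest risk.
#'
#' @param growth A [growth_reference()].
#' @param band A `weight_band`, band label or band index.
#' @return A data frame with columns `age_years`, `sex`, `weight_kg`
#'   (possibly zero rows).
#' @export
ages_in_band <- function(growth, band) {
  stopifnot(inherits(growth, "growth_reference"))
  band <- as_weight_band(band)
  ok <- growth$weight_kg >= 3 &
    band_index_for_weight(pmax(growth$weight_kg, 3)) == band$index
  res <- growth[ok, c("age_years", "sex", "weight_kg")]
  res <- res[order(res$age_years, res$sex), ]
  rownames(res) <- NULL
  class(res) <- "data.frame"
  res
}

#' Read a growth reference from CSV
#'
#' Expected columns: `age_years,sex,weight_kg,height_m,bmi`; `sex` is
#' `F`/`M`; `weight_kg` may be empty where `bmi` and `height_m` are given.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A [growth_reference()].
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  growth_reference(df)
}

#' Write a growth reference to CSV
#'
#' @param growth A [growth_reference()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_growth_csv <- function(growth, path) {
  stopifnot(inherits(growth, "growth_reference"))
  out <- as.data.frame(growth)
  # preserve the "derived for older ages" shape: blank weight where bmi+height carry it
  derived <- !is.na(out$bmi) & !is.na(out$height_m) &
    abs(out$weight_kg - out$bmi * out$height_m^2) < 1e-9
  out$weight_kg[derived] <- NA
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
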