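# Fixture builders and independent oracles shared across the suite.
# Oracles are deliberately written from first principles, independent of the
# package's own code paths.

# growth table carrying the published median values for an 18-year-old
# female (BMI 21.31 at 1.631 m ~ 56.7 kg) plus a newborn row
mini_growth <- function() {
  growth_reference(data.frame(
    age_years = c(0, 18, 0, 18),
    sex = c("F", "F", "M", "M"),
    weight_kg = c(3.2, NA, 3.3, 67.3),
    height_m = c(NA, 1.631, NA, 1.761),
    bmi = c(NA, 21.31, NA, 21.7),
    stringsAsFactors = FALSE
  ))
}

# linear growth curve w = 3 + 3 * age, both sexes identical
linear_growth <- function() {
  make_growth_reference(synth_config(growth_model = "linear"))
}

# minimal coefficient fixture: the published age-5 male incidence value
# embedded in a declining grid
anchored_coeffs <- function() {
  risk_coefficients(data.frame(
    age_years = rep(c(0, 5, 10, 20), 2),
    sex = rep(c("M", "F"), each = 4),
    endpoint = "incidence",
    excess_per_100k_per_0.1Gy = c(2563, 1816, 1445, 1000,
                                  3100, 2300, 1900, 1300),
    stringsAsFactors = FALSE
  ))
}

# hand-rolled linear interpolation with endpoint clamping (oracle for
# interpolate_coefficient; independent of stats::approx)
oracle_interp <- function(ages, vals, x) {
  o <- order(ages)
  ages <- ages[o]; vals <- vals[o]
  if (x <= ages[1]) return(vals[1])
  n <- length(ages)
  if (x >= ages[n]) return(vals[n])
  i <- max(which(ages <= x))
  if (ages[i] == x) return(vals[i])
  vals[i] + (vals[i + 1] - vals[i]) * (x - ages[i]) / (ages[i + 1] - ages[i])
}

# brute-force band lookup from the printed integer kilogram ranges
oracle_band_label <- function(weight_kg) {
  w <- round(weight_kg)
  if (w >= 3 && w <= 7) "3-7"
  else if (w <= 15) "8-15"
  else if (w <= 25) "16-25"
  else if (w <= 40) "26-40"
  else if (w <= 60) "41-60"
  else "60+"
}

# brute-force maximum-risk search over every (age, sex) in a band:
# recomputes membership, interpolation and dose scaling from scratch
oracle_band_max <- function(exam, band_label, growth, doses, coeffs,
                            endpoint = "incidence") {
  dose_row <- doses[doses$exam == exam & doses$band == band_label, ]
  stopifnot(nrow(dose_row) == 1)
  best <- NULL
  for (i in seq_len(nrow(growth))) {
    w <- growth$weight_kg[i]
    if (w < 3 || oracle_band_label(w) != band_label) next
    sub <- coeffs[coeffs$sex == growth$sex[i] & coeffs$endpoint == endpoint, ]
    cf <- oracle_interp(sub$age_years, sub$excess_per_100k, growth$age_years[i])
    risk <- dose_row$effective_dose_mSv / 100 * cf
    if (is.null(best) || risk > best$risk + 1e-12) {
      best <- list(risk = risk, age = growth$age_years[i], sex = growth$sex[i])
    }
  }
  best
}

expect_paedrad_error <- function(expr, class) {
  expect_error(expr, class = class)
}
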