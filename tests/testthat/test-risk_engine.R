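test_that("coefficients return exactly at grid ages and interpolate between", {
  co <- anchored_coeffs()
  expect_equal(interpolate_coefficient(co, 5, "M", "incidence"), 1816)
  simple <- risk_coefficients(data.frame(
    age_years = c(0, 10), sex = "M", endpoint = "incidence",
    excess_per_100k_per_0.1Gy = c(100, 50)))
  expect_equal(interpolate_coefficient(simple, 5, "M"), 75)
  expect_equal(interpolate_coefficient(simple, 2.5, "M"), 87.5)
  expect_paedrad_error(interpolate_coefficient(simple, 5, "F"),
                       "paedradrisk_lookup_error")
})

test_that("ages outside the grid clamp to the nearest grid age with a warning", {
  simple <- risk_coefficients(data.frame(
    age_years = c(5, 10), sex = "M", endpoint = "incidence",
    excess_per_100k_per_0.1Gy = c(100, 50)))
  expect_warning(lo <- interpolate_coefficient(simple, 2, "M"), "clamped")
  expect_equal(lo, 100)
  expect_warning(hi <- interpolate_coefficient(simple, 30, "M"), "clamped")
  expect_equal(hi, 50)
})

test_that("interpolation matches a brute-force interpolant at 1000 random ages", {
  set.seed(42)
  grid_ages <- c(0, 3, 7, 12, 18, 25, 30)
  vals_m <- 2000 * exp(-0.06 * grid_ages) * (1 + 0.1 * sin(grid_ages))
  vals_f <- 1.3 * vals_m
  co <- risk_coefficients(data.frame(
    age_years = rep(grid_ages, 2), sex = rep(c("M", "F"), each = 7),
    endpoint = "incidence",
    excess_per_100k_per_0.1Gy = c(vals_m, vals_f)))
  ages <- runif(1000, 0, 30)
  sexes <- sample(c("M", "F"), 1000, replace = TRUE)
  for (i in seq_along(ages)) {
    vals <- if (sexes[i] == "M") vals_m else vals_f
    expect_equal(interpolate_coefficient(co, ages[i], sexes[i]),
                 oracle_interp(grid_ages, vals, ages[i]),
                 tolerance = 1e-12)
  }
})

test_that("interpolation error vanishes as the grid refines on a smooth curve", {
  c0 <- 2563; lambda <- 0.05
  truth <- function(a) c0 * exp(-lambda * a)
  errs <- vapply(c(5, 1), function(h) {
    grid <- seq(0, 30, by = h)
    co <- risk_coefficients(data.frame(
      age_years = grid, sex = "M", endpoint = "incidence",
      excess_per_100k_per_0.1Gy = truth(grid)))
    q <- seq(0.25, 29.75, by = 0.25)
    max(abs(vapply(q, interpolate_coefficient, numeric(1),
                   coeffs = co, sex = "M") - truth(q)) / truth(q))
  }, numeric(1))
  expect_lt(errs[1], 0.01)   # 5-year spacing already under 1%
  expect_lt(errs[2], errs[1] / 10) # refinement shrinks the error
})

test_that("dose scaling is linear and recovers the worked example", {
  expect_equal(risk_from_dose(1, 1816), 18.16)
  expect_equal(risk_from_dose(0, 1816), 0)
  expect_equal(risk_from_dose(100, 1816), 1816) # reference dose
  for (a in c(0, 0.5, 2, 7)) {
    expect_equal(risk_from_dose(a * 0.4, 1200), a * risk_from_dose(0.4, 1200))
  }
  expect_paedrad_error(risk_from_dose(-1, 1816), "paedradrisk_invalid_argument")
})

test_that("one_in_n inverts the unrounded risk", {
  expect_equal(one_in_n(18.16), 5506.608, tolerance = 1e-6)
  expect_equal(one_in_n(100000), 1)
  expect_equal(one_in_n(1), 100000)
  expect_identical(one_in_n(0), Inf)
})

test_that("1-in-N is strictly decreasing in dose for a fixed coefficient", {
  doses <- seq(0.01, 5, length.out = 40)
  ns <- vapply(doses, function(d) one_in_n(risk_from_dose(d, 1816)), numeric(1))
  expect_true(all(diff(ns) < 0))
})

test_that("band maximum risk picks the highest-risk member deterministically", {
  g <- linear_growth() # band 16-25 holds ages 5, 6, 7, both sexes
  co <- make_coefficient_table(synth_config(
    coeff_params = list(sex_ratio = 1))) # decreasing in age, sexes equal
  d <- dose_table(data.frame(exam = "Test Exam", band = "16-25",
                             effective_dose_mSv = 0.5))
  est <- band_max_risk("Test Exam", "16-25", g, d, co)
  expect_equal(est$age_years, 5) # youngest member wins under decay
  expect_equal(est$sex, "F")     # ties (equal sexes) break to female
  expect_equal(est$excess_per_100k,
               0.5 / 100 * interpolate_coefficient(co, 5, "F"))
  expect_equal(est$band, "16-25")
})

test_that("single-member bands return that member's estimate", {
  g <- mini_growth() # 60+ holds only (18, M): 67.3 kg
  co <- anchored_coeffs()
  d <- dose_table(data.frame(exam = "Chest AP", band = "60+",
                             effective_dose_mSv = 0.033))
  est <- band_max_risk("Chest AP", "60+", g, d, co)
  expect_equal(est$age_years, 18)
  expect_equal(est$sex, "M")
  expect_equal(est$excess_per_100k,
               0.033 / 100 * oracle_interp(c(0, 5, 10, 20),
                                           c(2563, 1816, 1445, 1000), 18))
})

test_that("band maximum equals an independent brute-force search", {
  g <- synthetic_growth()
  co <- synthetic_coefficients()
  d <- rch_dose_table()
  for (lab in c("3-7", "16-25", "41-60", "60+")) {
    est <- band_max_risk("Chest AP", lab, g, d, co)
    oracle <- oracle_band_max("Chest AP", lab, g, d, co)
    expect_equal(est$excess_per_100k, oracle$risk, tolerance = 1e-12)
    expect_equal(est$age_years, oracle$age)
  }
})

test_that("a band with no representative age is an explicit error", {
  g <- linear_growth() # never reaches 60+
  d <- dose_table(data.frame(exam = "Chest AP", band = "60+",
                             effective_dose_mSv = 0.033))
  expect_paedrad_error(
    band_max_risk("Chest AP", "60+", g, d, synthetic_coefficients()),
    "paedradrisk_no_representative_age")
})

test_that("coefficient CSVs round-trip", {
  p <- withr::local_tempfile(fileext = ".csv")
  co <- anchored_coeffs()
  write_coefficients_csv(co, p)
  co2 <- read_coefficients_csv(p)
  expect_equal(interpolate_coefficient(co2, 5, "M"), 1816)
  expect_equal(co2$excess_per_100k, co$excess_per_100k)
})
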