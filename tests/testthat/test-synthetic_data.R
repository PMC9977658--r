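test_that("linear growth model follows its closed form", {
  g <- linear_growth() # w = 3 + 3 * age
  expect_equal(median_weight(g, 5, "M"), 18)
  expect_equal(median_weight(g, 0, "F"), 3)
  expect_equal(median_weight(g, 18, "M"), 57)
})

test_that("logistic defaults keep weights realistic and cover every band", {
  g <- make_growth_reference(synth_config())
  expect_true(all(g$weight_kg >= 3))
  w18 <- c(median_weight(g, 18, "F"), median_weight(g, 18, "M"))
  labels <- vapply(w18, function(w) band_for_weight(w)$label, character(1))
  expect_true(all(labels %in% c("41-60", "60+")))
  populated <- vapply(weight_bands()$label, function(b)
    nrow(ages_in_band(g, b)) > 0, logical(1))
  expect_true(all(populated))
})

test_that("growth generation is deterministic and rejects bad configurations", {
  expect_identical(make_growth_reference(synth_config(seed = 7)),
                   make_growth_reference(synth_config(seed = 7)))
  expect_paedrad_error(
    make_growth_reference(synth_config(growth_model = "linear",
                                       growth_params = list(slope = -1))),
    "paedradrisk_config_error")
  expect_paedrad_error(
    make_growth_reference(synth_config(growth_model = "linear",
                                       growth_params = list(w0 = 1))),
    "paedradrisk_config_error")
})

test_that("older synthetic ages exercise the BMI-height derivation", {
  g <- make_growth_reference(synth_config())
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_csv(g, path)
  raw <- utils::read.csv(path)
  old <- raw[raw$age_years >= 11, ]
  expect_true(all(is.na(old$weight_kg)))
  expect_true(all(!is.na(old$bmi) & !is.na(old$height_m)))
})

test_that("coefficient tables decay exponentially and anchor the reference value", {
  co <- make_coefficient_table(synth_config())
  expect_equal(interpolate_coefficient(co, 5, "M", "incidence"), 1816)
  # closed form at another grid age: c(10) = c(5) * exp(-5 * lambda)
  expect_equal(interpolate_coefficient(co, 10, "M", "incidence"),
               1816 * exp(-5 * 0.05), tolerance = 1e-12)
  # female scaled, mortality a fixed fraction
  expect_equal(interpolate_coefficient(co, 5, "F", "incidence"), 1816 * 1.35)
  expect_equal(interpolate_coefficient(co, 5, "M", "mortality"), 1816 * 0.5)
  expect_s3_class(co, "risk_coefficients") # constructor enforces invariants
  expect_paedrad_error(
    make_coefficient_table(synth_config(coeff_params = list(lambda = -0.1))),
    "paedradrisk_config_error")
})

test_that("synthetic charts validate cleanly and honour restrictions", {
  synth <- make_chart(synth_config())
  expect_length(validate_chart(synth$chart, synth$catalogue), 0)
  # geometric progression: factor 2 from band 0 to band 5 is x32
  e0 <- exposure_for(synth$chart, "Synthetic View 01", "3-7")
  e5 <- exposure_for(synth$chart, "Synthetic View 01", "60+")
  expect_equal(e5$mas / e0$mas, 32)

  restricted <- make_chart(synth_config(chart_params = list(restricted_frac = 1)))
  for (b in c("3-7", "8-15", "16-25")) {
    expect_paedrad_error(exposure_for(restricted$chart, "Synthetic View 01", b),
                         "paedradrisk_missing_exposure")
  }
  expect_no_error(exposure_for(restricted$chart, "Synthetic View 01", "26-40"))
})

test_that("pipeline recovers closed-form risk within interpolation error", {
  # with c(age) = c0 exp(-lambda age) on a 5-year grid, the full pipeline's
  # excess risk equals (D/100) c(age) to better than 1%
  lambda <- 0.05
  c0 <- 1816 * exp(5 * lambda)
  co <- make_coefficient_table(synth_config(
    coeff_params = list(ages = seq(0, 30, by = 5))))
  set.seed(11)
  for (i in 1:50) {
    age <- runif(1, 0, 30)
    dose <- runif(1, 0.001, 2)
    got <- risk_from_dose(dose, interpolate_coefficient(co, age, "M"))
    truth <- dose / 100 * c0 * exp(-lambda * age)
    expect_lt(abs(got - truth) / truth, 0.01)
  }
})

test_that("identical configurations write byte-identical input sets", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_synthetic_inputs(d1, synth_config(seed = 3))
  p2 <- write_synthetic_inputs(d2, synth_config(seed = 3))
  for (k in names(p1)) {
    expect_identical(readLines(p1[[k]]), readLines(p2[[k]]), label = k)
  }
  # and the files feed straight back into the readers
  g <- read_growth_csv(p1[["growth"]])
  co <- read_coefficients_csv(p1[["coefficients"]])
  ch <- read_chart_csv(p1[["chart"]])
  expect_s3_class(g, "growth_reference")
  expect_equal(interpolate_coefficient(co, 5, "M"), 1816)
  expect_length(validate_chart(ch, read_catalogue_json(p1[["catalogue"]])), 0)
})
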