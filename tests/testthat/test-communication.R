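test_that("Calman classification reproduces published examples", {
  expect_equal(classify_calman(1 / 283000), "Minimal")
  expect_equal(classify_calman(1 / 5507), "Low")
  expect_equal(classify_calman(1 / 9400), "Low")
  expect_equal(classify_calman(1 / 99700), "Very Low")
  expect_equal(classify_calman(1 / 2326000), "Negligible")
  expect_paedrad_error(classify_calman(0), "paedradrisk_invalid_argument")
  expect_paedrad_error(classify_calman(1.5), "paedradrisk_invalid_argument")
})

test_that("Calman bins partition (0, 1] and are monotone in probability", {
  edges <- 10^(-6:-2)
  sweep <- sort(c(10^seq(-8, 0, length.out = 200), edges, 1))
  cats <- classify_calman(sweep)
  expect_true(all(!is.na(cats))) # every probability maps somewhere
  severity <- match(cats, calman_table()$category)
  expect_true(all(diff(severity) >= 0)) # larger p never less severe
  # lower bound inclusive: exact powers of ten land in the upper bin
  expect_equal(classify_calman(1e-3), "Moderate")
  expect_equal(classify_calman(1e-6), "Minimal")
  expect_equal(classify_calman(1e-6 - 1e-12), "Negligible")
})

test_that("every published (1-in-N, category) pair classifies consistently", {
  d <- rch_dose_table()
  expect_gte(nrow(d), 100)
  got <- classify_calman(1 / d$published_one_in_n)
  expect_equal(got, d$published_category)
})

test_that("BERT converts dose to background-equivalent time", {
  expect_equal(bert(1.5), 1) # one year of background by definition
  expect_equal(bert(0), 0)
  expect_equal(bert(0.033) * 365.25, 8.03, tolerance = 1e-2) # ~8 days
  expect_equal(bert_display(0.033), "8.0 days")
  # unit selection: hours below 2 days, months beyond 3 months
  expect_match(bert_display(0.004), "hours$")
  expect_match(bert_display(1.5), "months$")
  expect_paedrad_error(bert(-1), "paedradrisk_invalid_argument")
})

test_that("flight-time equivalence closes the loop on its constants", {
  expect_equal(round(flight_hours(0.11)), 46) # Melbourne-London return
  expect_equal(flight_hours(0.00239), 1)
  expect_equal(flight_hours(0), 0)
})

test_that("bert and flight_hours are linear in dose", {
  d <- c(0.001, 0.05, 0.4, 2)
  for (a in c(0.5, 3)) {
    expect_equal(bert(a * d[1]), a * bert(d[1]))
    expect_equal(flight_hours(a * d), a * flight_hours(d))
  }
})

test_that("cumulative risk adds excess risks and re-classifies", {
  e1 <- patient_risk("Chest AP", 5, "M", dose_mSv = 1,
                     coeffs = anchored_coeffs(), growth = linear_growth(),
                     catalogue = NULL)$risk
  tot <- cumulative_risk(list(e1, e1))
  expect_equal(tot$excess_per_100k, 2 * 18.16)
  expect_equal(cumulative_risk(list(e1))$excess_per_100k, e1$excess_per_100k)
  # ten Very Low exposures cross into Low
  small <- lapply(1:10, function(i) {
    est <- e1; est$excess_per_100k <- 1.2; est
  })
  summed <- cumulative_risk(small)
  expect_equal(summed$excess_per_100k, 12)
  expect_equal(risk_category(summed), "Low")
  expect_equal(classify_calman(1.2 / 1e5), "Very Low")
  # mixed endpoints refuse to add
  e2 <- e1; e2$endpoint <- "mortality"
  expect_paedrad_error(cumulative_risk(list(e1, e2)),
                       "paedradrisk_invalid_argument")
  expect_paedrad_error(cumulative_risk(list()), "paedradrisk_invalid_argument")
})

test_that("display formatting follows the table and running-text conventions", {
  expect_equal(format_one_in_n(5506.6, "text"), "5507")
  expect_equal(format_one_in_n(165875, "table"), "166,000")
  expect_equal(format_one_in_n(9371, "table"), "9400")
  expect_equal(format_one_in_n(5506.6, "table"), "5500")
  expect_equal(format_one_in_n(Inf, "table"), "-")
})

test_that("summaries render deterministic strings, bounding sub-threshold doses", {
  pr <- patient_risk("Chest AP", 5, "M", dose_mSv = 1,
                     coeffs = anchored_coeffs(), growth = linear_growth(),
                     catalogue = NULL)
  d <- format_summary(pr)
  expect_equal(unname(d["one_in_n_text"]), "1 in 5507")
  expect_equal(unname(d["risk_per_100k"]), "18.2 per 100,000")
  expect_equal(unname(d["percent"]), "0.0182%")
  expect_equal(unname(d["category"]), "Low")

  low <- patient_risk("Knee AP and Lateral", 0, "F",
                      coeffs = anchored_coeffs(), growth = linear_growth(),
                      catalogue = NULL)
  dl <- format_summary(low)
  expect_equal(unname(dl["dose"]), "<0.001")
  expect_match(unname(dl["risk_per_100k"]), "^less than ")
})
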