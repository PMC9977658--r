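#' Configuration for the synthetic-data generator
#'
#' The generator produces download-free stand-ins with the statistical
#' structure the pipeline consumes: monotone median weight-for-age curves
#' for ages 0-18 by sex, age-declining risk-coefficient tables on a sparse
#' age grid, and weight-banded exposure charts with optional missing bands.
#' All outputs are deterministic closed forms; with `noise = 0` (the
#' default) the same configuration always yields byte-identical files.
#'
#' Growth models:
#' * `"logistic"` (default): monoexponential approach to an asymptote,
#'   `w(age) = w_inf - (w_inf - w0) * exp(-k * age)`, with female weights
#'   scaled by `sex_factor`. The defaults (`w0 = 3.3`, `w_inf = 68`,
#'   `k = 0.12`, `sex_factor = 0.97`) populate every weight band with at
#'   least one (age, sex) and keep all weights at or above 3 kg.
#' * `"linear"`: `w(age) = w0 + slope * age`.
#'
#' Coefficient model `"exponential_decay"`:
#' `c(age) = c0 * exp(-lambda * age)` for males, scaled by `sex_ratio` for
#' females, with mortality a fixed fraction of incidence. With
#' `anchor = TRUE` (default) `c0` is chosen so the male incidence
#' coefficient at age 5 equals 1816 per 100,000 per 0.1 Gy, the published
#' reference value used in the worked example.
#'
#' @param seed Integer seed; drives the jitter when `noise > 0`.
#' @param growth_model `"logistic"` or `"linear"`.
#' @param growth_params Named list overriding the model's defaults.
#' @param coeff_params Named list: `lambda` (per year, >= 0), `sex_ratio`,
#'   `mortality_fraction`, `ages` (grid), `anchor` and `c0`.
#' @param chart_params Named list: `n_views`, `mas0`, `factor` (geometric
#'   mAs progression across bands), `restricted_frac` (fraction of views
#'   missing their three lightest bands).
#' @param noise Relative jitter applied to growth weights (default 0).
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L,
                         growth_model = c("logistic", "linear"),
                         growth_params = list(),
                         coeff_params = list(),
                         chart_params = list(),
                         noise = 0) {
  growth_model <- match.arg(growth_model)
  gp_default <- if (growth_model == "logistic") {
    list(w0 = 3.3, w_inf = 68, k = 0.12, sex_factor = 0.97)
  } else {
    list(w0 = 3, slope = 3, sex_factor = 1)
  }
  cp_default <- list(lambda = 0.05, sex_ratio = 1.35, mortality_fraction = 0.5,
                     ages = c(0, 5, 10, 15, 20, 30), anchor = TRUE, c0 = 2000)
  hp_default <- list(n_views = 6, mas0 = 1, factor = 2, restricted_frac = 0)
  cfg <- list(
    seed = as.integer(seed),
    growth_model = growth_model,
    growth_params = utils::modifyList(gp_default, growth_params),
    coeff_params = utils::modifyList(cp_default, coeff_params),
    chart_params = utils::modifyList(hp_default, chart_params),
    noise = noise
  )
  class(cfg) <- "synth_config"
  cfg
}

synth_weight_curve <- function(cfg, ages, sex) {
  gp <- cfg$growth_params
  sf <- if (sex == "F") gp$sex_factor else 1
  w <- switch(cfg$growth_model,
    logistic = gp$w_inf - (gp$w_inf - gp$w0) * exp(-gp$k * ages),
    linear = gp$w0 + gp$slope * ages
  )
  w * sf
}

#' Generate a synthetic growth reference
#'
#' Produces integer ages 0-18 for both sexes with monotone median weights.
#' Ages 11-18 are emitted as (BMI, height) pairs with weight omitted —
#' mirroring published reference data, where weight-for-age stops at age
#' 10 — so the derivation `weight = BMI x height^2` is exercised on every
#' load. The synthetic height curve is
#' `h(age) = 1.80 - 1.30 * exp(-0.115 * age)` metres for both sexes.
#'
#' @param config A [synth_config()].
#' @return A [growth_reference()]. Clearly synthetic: not fitted to any
#'   published reference population.
#' @export
make_growth_reference <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  ages <- 0:18
  rows <- list()
  set.seed(config$seed)
  for (sex in c("F", "M")) {
    w <- synth_weight_curve(config, ages, sex)
    if (config$noise > 0) {
      w <- w * (1 + config$noise * stats::runif(length(w), -1, 1))
    }
    if (is.unsorted(w)) {
      pr_stop("configured growth parameters produce non-monotone weights",
              "paedradrisk_config_error")
    }
    if (any(w < 3)) {
      pr_stop("configured growth parameters produce weights below 3 kg",
              "paedradrisk_config_error")
    }
    h <- 1.80 - 1.30 * exp(-0.115 * ages)
    derived <- ages >= 11
    rows[[sex]] <- data.frame(
      age_years = ages, sex = sex,
      weight_kg = ifelse(derived, NA, w),
      height_m = ifelse(derived, h, NA),
      bmi = ifelse(derived, w / h^2, NA),
      stringsAsFactors = FALSE
    )
  }
  growth_reference(do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Generate a synthetic risk-coefficient table
#'
#' Exponentially age-declining coefficients on a sparse grid (see
#' [synth_config()]), for both sexes and both endpoints. With the default
#' anchoring, the male incidence coefficient at age 5 is exactly 1816 per
#' 100,000 per 0.1 Gy.
#'
#' @param config A [synth_config()].
#' @return A [risk_coefficients()] table.
#' @export
make_coefficient_table <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cp <- config$coeff_params
  if (cp$lambda < 0) {
    pr_stop("lambda must be >= 0: coefficients decline with age at exposure",
            "paedradrisk_config_error")
  }
  c0 <- if (isTRUE(cp$anchor)) 1816 * exp(5 * cp$lambda) else cp$c0
  grid <- expand.grid(age_years = cp$ages, sex = c("F", "M"),
                      endpoint = c("incidence", "mortality"),
                      stringsAsFactors = FALSE)
  male_inc <- c0 * exp(-cp$lambda * grid$age_years)
  val <- male_inc *
    ifelse(grid$sex == "F", cp$sex_ratio, 1) *
    ifelse(grid$endpoint == "mortality", cp$mortality_fraction, 1)
  grid$excess_per_100k_per_0.1Gy <- val
  risk_coefficients(grid)
}

#' Generate a synthetic exposure chart and matching catalogue
#'
#' Views carry geometrically increasing mAs across the six weight bands
#' (`mas = mas0 x factor^band_index`) and staggered kVp ranges. A leading
#' fraction of views (`restricted_frac`) is missing its three lightest
#' bands, emulating views only performed on larger children, so
#' missing-exposure handling is exercised. The catalogue holds one
#' single-view exam per view plus one combined exam over all views.
#'
#' @param config A [synth_config()].
#' @return A list with elements `chart` ([exposure_chart()]) and
#'   `catalogue` ([exam_catalogue()]).
#' @export
make_chart <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  hp <- config$chart_params
  n <- hp$n_views
  n_restricted <- ceiling(hp$restricted_frac * n)
  views <- lapply(seq_len(n), function(i) {
    mas <- hp$mas0 * i * hp$factor^(0:5)
    if (i <= n_restricted) mas[1:3] <- NA
    kvp_min <- 50 + 4 * (i - 1)
    row <- data.frame(view = sprintf("Synthetic View %02d", i),
                      kvp_min = kvp_min, kvp_max = kvp_min + 20,
                      stringsAsFactors = FALSE)
    mas_df <- as.data.frame(as.list(mas))
    names(mas_df) <- chart_mas_cols()
    cbind(row, mas_df, grid = FALSE, sid_cm = 100)
  })
  chart <- exposure_chart(do.call(rbind, views))
  exams <- lapply(seq_len(n), function(i) {
    nm <- sprintf("Synthetic View %02d", i)
    list(exam = sprintf("Synthetic Exam %02d", i),
         views = data.frame(name = nm, chart = nm, stringsAsFactors = FALSE),
         bands = if (i <= n_restricted) weight_bands()$label[4:6] else NULL)
  })
  all_views <- chart$views$view[(n_restricted + 1):n]
  exams[[n + 1]] <- list(
    exam = "Synthetic Combined Exam",
    views = data.frame(name = all_views, chart = all_views,
                       stringsAsFactors = FALSE),
    bands = NULL)
  list(chart = chart, catalogue = exam_catalogue(exams))
}

#' Write a full set of synthetic pipeline inputs
#'
#' Writes `growth.csv`, `coefficients.csv`, `chart.csv` and
#' `catalogue.json` into a directory, in the same schemas the readers
#' consume. Identical configurations produce byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param config A [synth_config()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_inputs <- function(dir, config = synth_config()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    growth = file.path(dir, "growth.csv"),
    coefficients = file.path(dir, "coefficients.csv"),
    chart = file.path(dir, "chart.csv"),
    catalogue = file.path(dir, "catalogue.json")
  )
  write_growth_csv(make_growth_reference(config), paths[["growth"]])
  write_coefficients_csv(make_coefficient_table(config), paths[["coefficients"]])
  synth <- make_chart(config)
  write_chart_csv(synth$chart, paths[["chart"]])
  write_catalogue_json(synth$catalogue, paths[["catalogue"]])
  invisible(paths)
}
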