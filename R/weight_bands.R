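#' Exposure-chart weight bands
#'
#' The institutional exposure chart stratifies children into six weight
#' bands: 3-7, 8-15, 16-25, 26-40, 41-60 and 60+ kg. The printed integer
#' ranges leave fractional gaps (e.g. 7.4 kg), so band membership uses the
#' contiguous half-open intervals \[3, 7.5), \[7.5, 15.5), \[15.5, 25.5),
#' \[25.5, 40.5), \[40.5, 60.5), \[60.5, Inf) — equivalent to rounding to
#' the nearest integer kilogram and applying the printed ranges.
#'
#' @return A data frame with one row per band: `index` (0-5), `label`,
#'   `lower_kg`, `upper_kg` (Inf for the open-ended top band).
#' @examples
#' weight_bands()
#' @export
weight_bands <- function() {
  data.frame(
    index = 0:5,
    label = c("3-7", "8-15", "16-25", "26-40", "41-60", "60+"),
    lower_kg = c(3, 7.5, 15.5, 25.5, 40.5, 60.5),
    upper_kg = c(7.5, 15.5, 25.5, 40.5, 60.5, Inf),
    stringsAsFactors = FALSE
  )
}

new_weight_band <- function(index) {
  bands <- weight_bands()
  row <- bands[bands$index == index, , drop = FALSE]
  structure(
    list(index = row$index, label = row$label,
         lower_kg = row$lower_kg, upper_kg = row$upper_kg),
    class = "weight_band"
  )
}

#' @export
print.weight_band <- function(x, ...) {
  cat(sprintf("<weight band %s kg (index %d)>\n", x$label, x$index))
  invisible(x)
}

#' @export
format.weight_band <- function(x, ...) x$label

#' Map a body weight to its exposure-chart weight band
#'
#' @param weight_kg Body weight in kilograms; must be at least 3 kg, the
#'   chart minimum. Weights below the chart raise an error rather than being
#'   clamped, because the chart makes no recommendation there.
#' @return A `weight_band` object (see [weight_bands()]).
#' @examples
#' band_for_weight(3.2)$label # "3-7"
#' band_for_weight(20)$label  # "16-25"
#' band_for_weight(65)$label  # "60+"
#' @export
band_for_weight <- function(weight_kg) {
  if (!is.numeric(weight_kg) || length(weight_kg) != 1L || !is.finite(weight_kg)) {
    pr_stop("`weight_kg` must be a single finite number",
            "paedradrisk_invalid_argument")
  }
  if (weight_kg < 3) {
    pr_stop(sprintf(
      "weight %.3g kg is below the 3 kg minimum of the exposure chart",
      weight_kg), "paedradrisk_below_chart")
  }
  new_weight_band(band_index_for_weight(weight_kg))
}

# vectorised internal form; assumes weights already validated >= 3
band_index_for_weight <- function(weight_kg) {
  bands <- weight_bands()
  idx <- findInterval(weight_kg, bands$lower_kg)
  bands$index[idx]
}

#' Look up a weight band by its label
#'
#' @param label One of `"3-7"`, `"8-15"`, `"16-25"`, `"26-40"`, `"41-60"`,
#'   `"60+"`.
#' @return A `weight_band` object.
#' @export
band_from_label <- function(label) {
  bands <- weight_bands()
  i <- match(label, bands$label)
  if (is.na(i)) {
    pr_stop(sprintf("unknown weight band label '%s' (expected one of %s)",
                    label, paste(bands$label, collapse = ", ")),
            "paedradrisk_lookup_error")
  }
  new_weight_band(bands$index[i])
}

as_weight_band <- function(band) {
  if (inherits(band, "weight_band")) return(band)
  if (is.character(band)) return(band_from_label(band))
  if (is.numeric(band) && band %in% 0:5) return(new_weight_band(as.integer(band)))
  pr_stop("`band` must be a weight_band, a band label or a band index 0-5",
          "paedradrisk_invalid_argument")
}
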