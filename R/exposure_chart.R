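#' Build a weight-banded exposure chart
#'
#' An exposure chart holds, per radiographic view, a kVp range and the
#' recommended mAs for each of the six weight bands (a missing cell means
#' the view is not performed in that band). kVp within the printed range is
#' resolved per band: explicit per-band values may be supplied; otherwise
#' the default rule interpolates linearly across band index,
#' `round(kvp_min + index/5 * (kvp_max - kvp_min))`, which reproduces the
#' chart's endpoint conventions (smallest band at `kvp_min`, largest at
#' `kvp_max`). Institutional charts are not necessarily linear in between,
#' so explicit `kvp_by_band` values take precedence when present.
#'
#' @param views A data frame with columns `view`, `kvp_min`, `kvp_max`,
#'   `mas_3_7`, `mas_8_15`, `mas_16_25`, `mas_26_40`, `mas_41_60`,
#'   `mas_60plus` (NA for missing cells), and optionally `grid` (logical),
#'   `sid_cm` (source-to-detector distance) and `kvp_0` .. `kvp_5`
#'   (explicit per-band kVp overrides).
#' @return An `exposure_chart` object.
#' @seealso [exposure_for()], [validate_chart()], [read_chart_csv()]
#' @export
exposure_chart <- function(views) {
  stopifnot(is.data.frame(views))
  mas_cols <- chart_mas_cols()
  need <- c("view", "kvp_min", "kvp_max", mas_cols)
  missing_cols <- setdiff(need, names(views))
  if (length(missing_cols)) {
    pr_stop(paste("chart missing columns:", paste(missing_cols, collapse = ", ")),
            "paedradrisk_invalid_argument")
  }
  views <- as.data.frame(views)
  views$view <- as.character(views$view)
  if (!"grid" %in% names(views)) views$grid <- FALSE
  if (!"sid_cm" %in% names(views)) views$sid_cm <- 100
  for (col in c("kvp_min", "kvp_max", mas_cols)) {
    views[[col]] <- as.numeric(views[[col]])
  }
  if (anyDuplicated(views$view)) {
    pr_stop("duplicate view names in chart", "paedradrisk_invalid_argument")
  }
  mas <- as.matrix(views[mas_cols])
  if (any(rowSums(!is.na(mas)) == 0)) {
    pr_stop("every view needs at least one mAs cell",
            "paedradrisk_invalid_argument")
  }
  structure(list(views = views), class = "exposure_chart")
}

chart_mas_cols <- function() {
  c("mas_3_7", "mas_8_15", "mas_16_25", "mas_26_40", "mas_41_60", "mas_60plus")
}

#' @export
print.exposure_chart <- function(x, ...) {
  cat(sprintf("<exposure chart: %d views, 6 weight bands>\n", nrow(x$views)))
  invisible(x)
}

# Alias expansion: a chart row like "Knee AP/Lateral" covers the views
# "Knee AP" and "Knee Lateral". Rule: strip a trailing parenthetical, then
# if the final whitespace token contains "/", split it and append each
# variant to the base. Exact row names always win over aliases.
chart_row_aliases <- function(view) {
  base <- sub("\\s*\\([^)]*\\)\\s*$", "", view)
  toks <- strsplit(base, " ", fixed = TRUE)[[1]]
  last <- toks[length(toks)]
  if (length(toks) > 1L && grepl("/", last, fixed = TRUE)) {
    stem <- paste(toks[-length(toks)], collapse = " ")
    paste(stem, strsplit(last, "/", fixed = TRUE)[[1]])
  } else {
    character(0)
  }
}

chart_resolve_view <- function(chart, view_name) {
  i <- match(view_name, chart$views$view)
  if (!is.na(i)) return(i)
  hits <- which(vapply(chart$views$view, function(v)
    view_name %in% chart_row_aliases(v), logical(1)))
  if (length(hits) == 1L) return(hits)
  if (length(hits) > 1L) {
    pr_stop(sprintf("view '%s' matches multiple chart rows (%s)", view_name,
                    paste(chart$views$view[hits], collapse = "; ")),
            "paedradrisk_lookup_error")
  }
  pr_stop(sprintf("view '%s' not found in exposure chart", view_name),
          "paedradrisk_lookup_error")
}

#' Resolve tube settings for a view and weight band
#'
#' @param chart An [exposure_chart()].
#' @param view_name A chart row name, or a single-view alias of a combined
#'   row (e.g. `"Knee Lateral"` matches the `"Knee AP/Lateral"` row).
#' @param band A `weight_band`, band label or index.
#' @return A list with `kvp` (integer) and `mas` (positive real).
#' @examples
#' chart <- rch_exposure_chart()
#' exposure_for(chart, "Chest AP", "3-7") # 70 kVp, 0.71 mAs
#' @export
exposure_for <- function(chart, view_name, band) {
  stopifnot(inherits(chart, "exposure_chart"))
  band <- as_weight_band(band)
  i <- chart_resolve_view(chart, view_name)
  row <- chart$views[i, ]
  mas <- row[[chart_mas_cols()[band$index + 1L]]]
  if (is.na(mas)) {
    pr_stop(sprintf(
      "view '%s' has no exposure for weight band %s (not performed in this band)",
      row$view, band$label), "paedradrisk_missing_exposure")
  }
  kvp_col <- paste0("kvp_", band$index)
  kvp <- if (kvp_col %in% names(row) && !is.na(row[[kvp_col]])) {
    as.integer(row[[kvp_col]])
  } else {
    as.integer(round(row$kvp_min + band$index / 5 * (row$kvp_max - row$kvp_min)))
  }
  list(kvp = kvp, mas = as.numeric(mas))
}

#' Build an examination catalogue
#'
#' An examination is an ordered list of views; each view may name the chart
#' row that carries its exposure when the two differ (e.g. the skeletal
#' survey's "Lateral Sternum" view uses the "Sternum Lateral" chart row).
#' Examinations restricted to a subset of weight bands (swimmers views,
#' breathing laterals) declare the band labels they cover.
#'
#' @param exams A list; each element is `list(exam = <name>, views =
#'   <data.frame with columns name, chart>, bands = <band labels or NULL>)`.
#' @return An `exam_catalogue` object.
#' @export
exam_catalogue <- function(exams) {
  stopifnot(is.list(exams))
  names(exams) <- vapply(exams, function(e) e$exam, character(1))
  for (e in exams) {
    if (!is.data.frame(e$views) || nrow(e$views) == 0) {
      pr_stop(sprintf("exam '%s' has no views", e$exam),
              "paedradrisk_invalid_argument")
    }
  }
  structure(list(exams = exams), class = "exam_catalogue")
}

#' @export
print.exam_catalogue <- function(x, ...) {
  cat(sprintf("<exam catalogue: %d examinations>\n", length(x$exams)))
  invisible(x)
}

catalogue_exam <- function(catalogue, exam_name) {
  e <- catalogue$exams[[exam_name]]
  if (is.null(e)) {
    pr_stop(sprintf("unknown examination '%s'", exam_name),
            "paedradrisk_lookup_error")
  }
  e
}

#' Views performed in an examination
#'
#' @param catalogue An [exam_catalogue()].
#' @param exam_name Examination name.
#' @return Character vector of view names, in chart order.
#' @export
views_for_exam <- function(catalogue, exam_name) {
  stopifnot(inherits(catalogue, "exam_catalogue"))
  catalogue_exam(catalogue, exam_name)$views$name
}

#' Weight bands an examination covers
#'
#' @param catalogue An [exam_catalogue()].
#' @param exam_name Examination name.
#' @return Integer band indices (0-5) the exam is defined for.
#' @export
exam_bands <- function(catalogue, exam_name) {
  stopifnot(inherits(catalogue, "exam_catalogue"))
  e <- catalogue_exam(catalogue, exam_name)
  if (is.null(e$bands)) 0:5 else
    unname(vapply(e$bands, function(b) as_weight_band(b)$index, integer(1)))
}

#' Validate an exposure chart (and optionally a catalogue) for consistency
#'
#' Checks performed: `kvp_min <= kvp_max`; all present mAs values positive;
#' mAs non-decreasing across weight bands (heavier patients never get less
#' tube output); every catalogue view resolvable against the chart.
#' Problems are reported as findings, not raised as errors.
#'
#' @param chart An [exposure_chart()].
#' @param catalogue Optional [exam_catalogue()] to cross-check.
#' @return Character vector of findings; empty when the chart is consistent.
#' @export
validate_chart <- function(chart, catalogue = NULL) {
  stopifnot(inherits(chart, "exposure_chart"))
  findings <- character(0)
  v <- chart$views
  mas <- as.matrix(v[chart_mas_cols()])
  for (i in seq_len(nrow(v))) {
    if (v$kvp_min[i] > v$kvp_max[i]) {
      findings <- c(findings, sprintf(
        "view '%s': kvp_min (%g) exceeds kvp_max (%g)",
        v$view[i], v$kvp_min[i], v$kvp_max[i]))
    }
    row_mas <- mas[i, ]
    if (any(row_mas[!is.na(row_mas)] <= 0)) {
      findings <- c(findings, sprintf("view '%s': non-positive mAs", v$view[i]))
    }
    present <- row_mas[!is.na(row_mas)]
    if (length(present) > 1L && is.unsorted(present)) {
      findings <- c(findings, sprintf(
        "view '%s': mAs decreases across weight bands", v$view[i]))
    }
  }
  if (!is.null(catalogue)) {
    for (e in catalogue$exams) {
      for (cv in e$views$chart) {
        ok <- tryCatch({ chart_resolve_view(chart, cv); TRUE },
                       error = function(err) FALSE)
        if (!ok) {
          findings <- c(findings, sprintf(
            "exam '%s' references unknown view '%s'", e$exam, cv))
        }
      }
    }
  }
  findings
}

#' Read an exposure chart from CSV
#'
#' Expected columns: `view,kvp_min,kvp_max,mas_3_7,mas_8_15,mas_16_25,`
#' `mas_26_40,mas_41_60,mas_60plus,grid,sid_cm`, with empty cells where the
#' chart prints a dash. Optional `kvp_0` .. `kvp_5` columns carry explicit
#' per-band kVp choices.
#'
#' @param path Path to a CSV file.
#' @return An [exposure_chart()].
#' @export
read_chart_csv <- function(path) {
  exposure_chart(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an exposure chart to CSV
#'
#' @param chart An [exposure_chart()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chart_csv <- function(chart, path) {
  stopifnot(inherits(chart, "exposure_chart"))
  utils::write.csv(chart$views, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an examination catalogue from JSON
#'
#' The JSON maps each exam to its view list; each view has a `name` and an
#' optional `chart` row alias, and an exam may declare a `bands` restriction
#' (band labels).
#'
#' @param path Path to a JSON file.
#' @return An [exam_catalogue()].
#' @export
read_catalogue_json <- function(path) {
  raw <- jsonlite::read_json(path)
  exams <- lapply(raw$exams, function(e) {
    views <- do.call(rbind, lapply(e$views, function(v) {
      data.frame(name = v$name,
                 chart = if (is.null(v$chart)) v$name else v$chart,
                 stringsAsFactors = FALSE)
    }))
    list(exam = e$exam, views = views,
         bands = if (is.null(e$bands)) NULL else unlist(e$bands))
  })
  exam_catalogue(exams)
}

#' Write an examination catalogue to JSON
#'
#' @param catalogue An [exam_catalogue()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalogue_json <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "exam_catalogue"))
  out <- list(exams = lapply(unname(catalogue$exams), function(e) {
    list(exam = e$exam,
         views = lapply(seq_len(nrow(e$views)), function(i)
           list(name = e$views$name[i], chart = e$views$chart[i])),
         bands = e$bands)
  }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null", pretty = TRUE)
  invisible(path)
}
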