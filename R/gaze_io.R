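#' Default column dialect for fixation tables
#'
#' Tracker exports name their columns differently; a dialect maps the
#' canonical field names used throughout the package to the column names
#' found in a particular file. The default matches a generic fixation
#' report with columns `participant`, `trial`, `trial_index`, `onset`,
#' `duration`, `x`, `y`.
#'
#' @return Named character vector: canonical name -> file column name.
#' @export
default_fixation_dialect <- function() {
  c(participant_id = "participant",
    trial_id = "trial",
    trial_index = "trial_index",
    onset_ms = "onset",
    duration_ms = "duration",
    x_px = "x",
    y_px = "y")
}

#' Read a fixation-event table
#'
#' Parses a CSV or TSV fixation report (one row per fixation) into the
#' canonical fixation tibble: `participant_id`, `trial_id`, `trial_index`,
#' `onset_ms`, `duration_ms`, `x_px`, `y_px`. Rows are sorted by
#' (participant, trial_index, onset) with a stable sort, so reading a
#' row-shuffled copy of the same file yields identical output.
#'
#' @param path Path to a `.csv` or `.tsv`/`.txt` file with a header row.
#' @param dialect Named character vector mapping canonical field names to
#'   the file's column names; see [default_fixation_dialect()].
#' @param absolute_time If `TRUE`, onsets in the file are absolute
#'   timestamps; they are converted to trial-relative milliseconds by
#'   subtracting each (participant, trial)'s first onset.
#' @return Tibble of fixations, one row per event.
#' @export
read_fixation_table <- function(path, dialect = default_fixation_dialect(),
                                absolute_time = FALSE) {
  if (!file.exists(path)) {
    abort(sprintf("fixation file not found: %s", path), class = "gazestrat_io_error")
  }
  need <- default_fixation_dialect()
  missing_map <- setdiff(names(need), names(dialect))
  if (length(missing_map) > 0) {
    abort(sprintf("dialect does not map canonical column(s): %s",
                  paste(missing_map, collapse = ", ")),
          class = "gazestrat_format_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "tsv" || ext == "txt") {
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  } else {
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE)
  }
  absent <- setdiff(unname(dialect[names(need)]), names(raw))
  if (length(absent) > 0) {
    abort(sprintf("fixation table is missing column(s): %s",
                  paste(absent, collapse = ", ")),
          class = "gazestrat_format_error")
  }
  out <- tibble::tibble(
    participant_id = as.character(raw[[dialect[["participant_id"]]]]),
    trial_id = as.character(raw[[dialect[["trial_id"]]]]),
    trial_index = parse_numeric_col(raw[[dialect[["trial_index"]]]],
                                    dialect[["trial_index"]]),
    onset_ms = parse_numeric_col(raw[[dialect[["onset_ms"]]]], dialect[["onset_ms"]]),
    duration_ms = parse_numeric_col(raw[[dialect[["duration_ms"]]]],
                                    dialect[["duration_ms"]]),
    x_px = parse_numeric_col(raw[[dialect[["x_px"]]]], dialect[["x_px"]]),
    y_px = parse_numeric_col(raw[[dialect[["y_px"]]]], dialect[["y_px"]])
  )
  validate_fixations(out)
  if (absolute_time) {
    out <- out |>
      dplyr::group_by(.data$participant_id, .data$trial_id) |>
      dplyr::mutate(onset_ms = .data$onset_ms - min(.data$onset_ms)) |>
      dplyr::ungroup()
  }
  out[order(out$participant_id, out$trial_index, out$onset_ms, method = "radix"), ]
}

parse_numeric_col <- function(x, col) {
  val <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(val) & !is.na(x))
  if (length(bad) > 0) {
    # +1 for the header line
    abort(sprintf("non-numeric value '%s' in column '%s' at line %d",
                  x[bad[1]], col, bad[1] + 1L),
          class = "gazestrat_parse_error")
  }
  val
}

validate_fixations <- function(fix) {
  if (any(is.na(fix$duration_ms)) || any(fix$duration_ms < 0)) {
    abort("fixation durations must be present and non-negative",
          class = "gazestrat_validation_error")
  }
  if (any(is.na(fix$onset_ms)) || any(fix$onset_ms < 0)) {
    abort("fixation onsets must be present and non-negative",
          class = "gazestrat_validation_error")
  }
  if (any(!is.finite(fix$x_px)) || any(!is.finite(fix$y_px))) {
    abort("fixation coordinates must be finite", class = "gazestrat_validation_error")
  }
  invisible(fix)
}

#' Write a fixation table in the default dialect
#'
#' @param fix Canonical fixation tibble.
#' @param path Output `.csv` or `.tsv` path.
#' @return `path`, invisibly.
#' @export
write_fixation_table <- function(fix, path) {
  out <- fix[, names(default_fixation_dialect())]
  names(out) <- unname(default_fixation_dialect())
  write_table(out, path)
}

#' Write a result table to CSV, TSV or JSON
#'
#' All of the pipeline's tabular outputs (gaze metrics, QC reports, cluster
#' labels, Steiger results, forest-plot data) are written through this one
#' function so the round-trip property `read(write(x)) == x` can be asserted
#' uniformly. Numeric values are written in full precision.
#'
#' @param x Data frame to write (empty data frames produce a header-only file).
#' @param path Output path; the format is taken from the extension unless
#'   `format` is given.
#' @param format One of `"csv"`, `"tsv"`, `"json"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("auto", "csv", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", json = "json",
                     abort("cannot infer table format from extension",
                           class = "gazestrat_io_error"))
  }
  x <- as.data.frame(x)
  switch(format,
    csv = readr::write_csv(x, path, progress = FALSE),
    tsv = readr::write_tsv(x, path, progress = FALSE),
    json = jsonlite::write_json(x, path, dataframe = "rows", auto_unbox = TRUE,
                                digits = NA)
  )
  invisible(path)
}

#' Read a table written by [write_table()]
#'
#' @param path Path to a `.csv`, `.tsv` or `.json` table.
#' @return Tibble.
#' @export
read_table_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    tsv = , txt = readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    json = tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE)),
    abort("unsupported table format", class = "gazestrat_io_error")
  )
}

#' Read a cognitive score table
#'
#' One row per participant, one named column per test score. The
#' participant-id column is matched case-insensitively against
#' `participant`/`participant_id`.
#'
#' @param path CSV/TSV path.
#' @return Tibble with a `participant_id` character column and numeric
#'   score columns.
#' @export
read_score_table <- function(path) {
  tbl <- read_table_file(path)
  idc <- which(tolower(names(tbl)) %in% c("participant", "participant_id"))
  if (length(idc) == 0) {
    abort("score table needs a participant/participant_id column",
          class = "gazestrat_format_error")
  }
  names(tbl)[idc[1]] <- "participant_id"
  tbl$participant_id <- as.character(tbl$participant_id)
  if (anyDuplicated(tbl$participant_id)) {
    abort("score table has duplicated participants", class = "gazestrat_validation_error")
  }
  score_cols <- setdiff(names(tbl), "participant_id")
  for (sc in score_cols) {
    if (!is.numeric(tbl[[sc]])) tbl[[sc]] <- parse_numeric_col(tbl[[sc]], sc)
    if (any(!is.finite(tbl[[sc]]) & !is.na(tbl[[sc]]))) {
      abort(sprintf("non-finite scores in column '%s'", sc),
            class = "gazestrat_validation_error")
    }
  }
  tbl[, c("participant_id", score_cols)]
}
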