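#' AOI labels
#'
#' Canonical label sets for the display's areas of interest: the nine matrix
#' cells (`M_r_c`, row/column indices 0..2), the eight answer choices
#' (`A_k`, k = 0..7), the pooled answer region (`ANS`) used by the scanpath
#' clustering, and `OUT` for fixations landing in no AOI.
#'
#' @return Character vector of labels.
#' @export
aoi_matrix_labels <- function() {
  g <- expand.grid(col = 0:2, row = 0:2)
  sprintf("M_%d_%d", g$row, g$col)
}

#' @rdname aoi_matrix_labels
#' @export
aoi_answer_labels <- function() sprintf("A_%d", 0:7)

#' @rdname aoi_matrix_labels
#' @export
aoi10_labels <- function() c(aoi_matrix_labels(), "ANS")

#' @rdname aoi_matrix_labels
#' @export
aoi17_labels <- function() c(aoi_matrix_labels(), aoi_answer_labels())

is_matrix_aoi <- function(x) startsWith(x, "M_")
is_answer_aoi <- function(x) startsWith(x, "A_")

#' Construct an AOI layout
#'
#' An AOI layout holds the pixel rectangles of the nine matrix cells (a 3x3
#' problem grid on the left of the screen) and the eight answer choices (a
#' 2x4 grid on the right). Rectangles are half-open, `[x0, x1) x [y0, y1)`,
#' so a point on a shared edge belongs to exactly one rectangle; coordinates
#' are screen pixels with the origin at the top-left.
#'
#' @param matrix_cells Tibble with columns `row`, `col` (0..2), `x0`, `y0`,
#'   `x1`, `y1`; exactly 9 rows.
#' @param answer_choices Tibble with columns `choice` (0..7), `x0`, `y0`,
#'   `x1`, `y1`; exactly 8 rows.
#' @param screen Integer vector `c(width, height)` in pixels.
#' @return An object of class `aoi_layout`.
#' @export
aoi_layout <- function(matrix_cells, answer_choices, screen) {
  matrix_cells <- tibble::as_tibble(matrix_cells)
  answer_choices <- tibble::as_tibble(answer_choices)
  matrix_cells$label <- sprintf("M_%d_%d", matrix_cells$row, matrix_cells$col)
  answer_choices$label <- sprintf("A_%d", answer_choices$choice)
  layout <- structure(
    list(matrix_cells = matrix_cells, answer_choices = answer_choices,
         screen = as.numeric(screen)),
    class = "aoi_layout"
  )
  validate_aoi_layout(layout)
  layout
}

layout_rects <- function(layout) {
  dplyr::bind_rows(
    layout$matrix_cells[, c("label", "x0", "y0", "x1", "y1")],
    layout$answer_choices[, c("label", "x0", "y0", "x1", "y1")]
  )
}

#' Validate an AOI layout
#'
#' Checks cardinality (9 matrix cells, 8 answer choices), unique labels,
#' pairwise non-overlap under the half-open convention, and containment in
#' the screen bounds.
#'
#' @param layout An `aoi_layout`.
#' @return The layout, invisibly; errors describe the first violation found.
#' @export
validate_aoi_layout <- function(layout) {
  if (nrow(layout$matrix_cells) != 9L) {
    abort(sprintf("AOI layout must have 9 matrix cells, found %d",
                  nrow(layout$matrix_cells)), class = "gazestrat_layout_error")
  }
  if (nrow(layout$answer_choices) != 8L) {
    abort(sprintf("AOI layout must have 8 answer choices, found %d",
                  nrow(layout$answer_choices)), class = "gazestrat_layout_error")
  }
  if (!setequal(layout$matrix_cells$label, aoi_matrix_labels())) {
    abort("matrix cells must cover (row, col) in {0,1,2} x {0,1,2} exactly once",
          class = "gazestrat_layout_error")
  }
  if (!setequal(layout$answer_choices$label, aoi_answer_labels())) {
    abort("answer choices must cover indices 0..7 exactly once",
          class = "gazestrat_layout_error")
  }
  rects <- layout_rects(layout)
  if (any(rects$x1 <= rects$x0) || any(rects$y1 <= rects$y0)) {
    abort("every AOI rectangle must have positive width and height",
          class = "gazestrat_layout_error")
  }
  if (any(rects$x0 < 0) || any(rects$y0 < 0) ||
      any(rects$x1 > layout$screen[1]) || any(rects$y1 > layout$screen[2])) {
    abort("AOI rectangles must lie inside the screen bounds",
          class = "gazestrat_layout_error")
  }
  n <- nrow(rects)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      overlap_x <- rects$x0[i] < rects$x1[j] && rects$x0[j] < rects$x1[i]
      overlap_y <- rects$y0[i] < rects$y1[j] && rects$y0[j] < rects$y1[i]
      if (overlap_x && overlap_y) {
        abort(sprintf("AOI rectangles overlap: %s and %s",
                      rects$label[i], rects$label[j]),
              class = "gazestrat_layout_error")
      }
    }
  }
  invisible(layout)
}

#' @export
print.aoi_layout <- function(x, ...) {
  cat(sprintf("<aoi_layout> screen %dx%d px, 9 matrix cells + 8 answer choices\n",
              x$screen[1], x$screen[2]))
  invisible(x)
}

#' Bundled default AOI layout and item key
#'
#' A plausible stand-in geometry for a matrix reasoning display: a 3x3
#' problem grid on the left half of a 1680x1050 screen and a 2x4 answer
#' bank on the right. The stimulus geometry of the original apparatus is
#' not published, so this layout is synthetic; any real study should load
#' its own layout with [load_aoi_layout()].
#'
#' The item key lists 21 trials: 3 practice items (`P1`..`P3`, excluded
#' from all metrics) followed by 18 scored items (`T01`..`T18`), each with
#' a fixed correct answer choice.
#'
#' @return A list with elements `layout` (an `aoi_layout`) and `keys`
#'   (a tibble: `trial_id`, `correct_choice`, `is_practice`).
#' @export
default_aoi_layout <- function() {
  cell <- 190
  gap <- 10
  mx0 <- 90; my0 <- 225
  grid <- expand.grid(col = 0:2, row = 0:2)
  matrix_cells <- tibble::tibble(
    row = grid$row, col = grid$col,
    x0 = mx0 + grid$col * (cell + gap),
    y0 = my0 + grid$row * (cell + gap),
    x1 = mx0 + grid$col * (cell + gap) + cell,
    y1 = my0 + grid$row * (cell + gap) + cell
  )
  aw <- 160; ah <- 160
  ax0 <- 900; ay0 <- 350
  agrid <- expand.grid(c = 0:3, r = 0:1)
  answer_choices <- tibble::tibble(
    choice = 0:7,
    x0 = ax0 + agrid$c * (aw + gap),
    y0 = ay0 + agrid$r * (ah + gap),
    x1 = ax0 + agrid$c * (aw + gap) + aw,
    y1 = ay0 + agrid$r * (ah + gap) + ah
  )
  layout <- aoi_layout(matrix_cells, answer_choices, screen = c(1680, 1050))
  keys <- default_item_keys()
  list(layout = layout, keys = keys)
}

default_item_keys <- function() {
  # fixed arbitrary answer key; spread over the 8 choices
  correct <- c(3, 5, 0, 2, 7, 1, 4, 6, 0, 3, 5, 2, 1, 7, 6, 4, 2, 0, 5, 3, 1)
  tibble::tibble(
    trial_id = c(sprintf("P%d", 1:3), sprintf("T%02d", 1:18)),
    correct_choice = correct,
    is_practice = c(rep(TRUE, 3), rep(FALSE, 18))
  )
}

#' Load an AOI layout and item key from a config file
#'
#' Reads a YAML or JSON description of the display geometry and the
#' per-item answer key, and validates it (cardinality, overlaps, bounds,
#' key range). The bundled default layout is available as
#' `system.file("extdata", "default_layout.yaml", package = "gazestrat")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file with top-level
#'   fields `screen`, `matrix_cells`, `answer_choices`, `item_keys`.
#' @return A list with elements `layout` and `keys`, as in
#'   [default_aoi_layout()].
#' @export
load_aoi_layout <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("layout file not found: %s", path), class = "gazestrat_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(sprintf("unsupported layout format '.%s' (use yaml or json)", ext),
          class = "gazestrat_io_error")
  )
  for (field in c("screen", "matrix_cells", "answer_choices", "item_keys")) {
    if (is.null(cfg[[field]])) {
      abort(sprintf("layout config is missing field '%s'", field),
            class = "gazestrat_layout_error")
    }
  }
  to_tbl <- function(x) {
    if (is.data.frame(x)) tibble::as_tibble(x) else dplyr::bind_rows(lapply(x, tibble::as_tibble))
  }
  keys <- to_tbl(cfg$item_keys)
  if (!all(c("trial_id", "correct_choice") %in% names(keys))) {
    abort("item_keys must have trial_id and correct_choice",
          class = "gazestrat_layout_error")
  }
  if (is.null(keys$is_practice)) keys$is_practice <- FALSE
  keys$trial_id <- as.character(keys$trial_id)
  keys$correct_choice <- as.integer(keys$correct_choice)
  keys$is_practice <- as.logical(keys$is_practice)
  bad <- keys$correct_choice < 0L | keys$correct_choice > 7L | is.na(keys$correct_choice)
  if (any(bad)) {
    abort(sprintf("correct_choice out of range 0..7 for trial(s): %s",
                  paste(keys$trial_id[bad], collapse = ", ")),
          class = "gazestrat_layout_error")
  }
  if (anyDuplicated(keys$trial_id)) {
    abort("item_keys has duplicated trial ids", class = "gazestrat_layout_error")
  }
  layout <- aoi_layout(to_tbl(cfg$matrix_cells), to_tbl(cfg$answer_choices),
                       screen = unlist(cfg$screen))
  list(layout = layout, keys = keys)
}

#' Write an AOI layout (plus item key) to YAML or JSON
#'
#' @param layout An `aoi_layout`.
#' @param keys Item-key tibble (`trial_id`, `correct_choice`, `is_practice`).
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_aoi_layout <- function(layout, keys, path) {
  cfg <- list(
    screen = as.integer(layout$screen),
    matrix_cells = lapply(seq_len(9), function(i)
      as.list(layout$matrix_cells[i, c("row", "col", "x0", "y0", "x1", "y1")])),
    answer_choices = lapply(seq_len(8), function(i)
      as.list(layout$answer_choices[i, c("choice", "x0", "y0", "x1", "y1")])),
    item_keys = lapply(seq_len(nrow(keys)), function(i)
      as.list(keys[i, c("trial_id", "correct_choice", "is_practice")]))
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("unsupported layout format (use yaml or json)", class = "gazestrat_io_error")
  }
  invisible(path)
}
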