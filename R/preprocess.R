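#' Tag fixations with their AOI
#'
#' Assigns each fixation the label of the AOI rectangle containing its
#' coordinates, or `OUT` when no rectangle contains them. Rectangles are
#' half-open (`x0 <= x < x1`, `y0 <= y < y1`), so a point on a shared edge
#' belongs to exactly one rectangle and the tag is a deterministic function
#' of the coordinates alone.
#'
#' @param fix Canonical fixation tibble (see [read_fixation_table()]).
#' @param layout A validated `aoi_layout`.
#' @return `fix` with two added columns: `aoi` (label) and `aoi_kind`
#'   (`"matrix"`, `"answer"`, or `"outside"`).
#' @export
tag_fixations <- function(fix, layout) {
  rects <- layout_rects(layout)
  aoi <- rep("OUT", nrow(fix))
  for (i in seq_len(nrow(rects))) {
    inside <- fix$x_px >= rects$x0[i] & fix$x_px < rects$x1[i] &
      fix$y_px >= rects$y0[i] & fix$y_px < rects$y1[i]
    aoi[inside] <- rects$label[i]
  }
  fix$aoi <- aoi
  fix$aoi_kind <- dplyr::case_when(
    is_matrix_aoi(aoi) ~ "matrix",
    is_answer_aoi(aoi) ~ "answer",
    TRUE ~ "outside"
  )
  fix
}

#' Filter one trial's tagged fixations
#'
#' Applies the standard fixation filters in order: (1) the first raw
#' fixation of the trial is dropped unconditionally, (2) fixations outside
#' every AOI are dropped, (3) fixations shorter than the minimum duration
#' are dropped. The default duration rule is inclusive (`>= 100` ms)
#' because recorders typically enforce a 100 ms minimum event duration and
#' a strict rule would erratically drop boundary events; `strict = TRUE`
#' switches to `> min_duration_ms`.
#'
#' @param trial_fix Tagged fixations of a single trial, in time order.
#' @param min_duration_ms Minimum retained duration (ms).
#' @param drop_first Drop the first raw fixation of the trial.
#' @param drop_outside Drop `OUT`-tagged fixations.
#' @param strict Use a strict `>` duration rule.
#' @return The retained fixations (possibly zero rows).
#' @export
filter_trial <- function(trial_fix, min_duration_ms = 100, drop_first = TRUE,
                         drop_outside = TRUE, strict = FALSE) {
  if (nrow(trial_fix) == 0) return(trial_fix)
  ord <- order(trial_fix$onset_ms, method = "radix")
  trial_fix <- trial_fix[ord, ]
  if (drop_first) trial_fix <- trial_fix[-1, , drop = FALSE]
  if (drop_outside) {
    trial_fix <- trial_fix[trial_fix$aoi != "OUT", , drop = FALSE]
  }
  keep <- if (strict) trial_fix$duration_ms > min_duration_ms
          else trial_fix$duration_ms >= min_duration_ms
  trial_fix[keep, , drop = FALSE]
}

#' Filter all trials of a tagged fixation table
#'
#' Applies [filter_trial()] within every (participant, trial) group and
#' drops practice trials when an item key is supplied. Trials left empty by
#' the filters are simply absent from the result; [empty_trials()] lists
#' them.
#'
#' @param fix Tagged fixation tibble.
#' @param keys Optional item-key tibble; practice trials are removed.
#' @inheritParams filter_trial
#' @return Filtered fixation tibble.
#' @export
filter_fixations <- function(fix, keys = NULL, min_duration_ms = 100,
                             drop_first = TRUE, drop_outside = TRUE,
                             strict = FALSE) {
  if (!is.null(keys)) {
    scored <- keys$trial_id[!keys$is_practice]
    fix <- fix[fix$trial_id %in% scored, , drop = FALSE]
  }
  # vectorized equivalent of filter_trial() per (participant, trial)
  fix <- fix[order(fix$participant_id, fix$trial_id, fix$onset_ms,
                   method = "radix"), , drop = FALSE]
  keep <- rep(TRUE, nrow(fix))
  if (drop_first) {
    first_of_trial <- !duplicated(paste(fix$participant_id, fix$trial_id,
                                        sep = "\r"))
    keep <- keep & !first_of_trial
  }
  if (drop_outside) keep <- keep & fix$aoi != "OUT"
  keep <- keep & if (strict) fix$duration_ms > min_duration_ms else
    fix$duration_ms >= min_duration_ms
  fix[keep, , drop = FALSE]
}

#' Trials emptied by filtering
#'
#' @param raw Tagged (unfiltered) fixation tibble, practice trials removed.
#' @param filtered Output of [filter_fixations()].
#' @return Tibble of (participant_id, trial_id) pairs present in `raw` but
#'   absent after filtering.
#' @export
empty_trials <- function(raw, filtered) {
  dplyr::anti_join(
    dplyr::distinct(raw, .data$participant_id, .data$trial_id),
    dplyr::distinct(filtered, .data$participant_id, .data$trial_id),
    by = c("participant_id", "trial_id")
  )
}

#' Participant-level quality control
#'
#' Excludes participants that fail any of three rules: (1) a mean raw
#' fixation count per scored trial below `min_fix_per_trial` (the classic
#' "two or fewer fixations per trial" exclusion), (2) a validity ratio
#' below `valid_ratio_min`, and (3) any score further than `score_sd_limit`
#' standard deviations from the cohort mean of that score, evaluated per
#' score column on the participants that survive rules 1-2. A zero-SD score
#' column excludes nobody.
#'
#' The validity ratio is taken from `tracking_ratio` (a named numeric
#' vector, typically a recorder-reported tracking percentage in `[0, 1]`)
#' when supplied; otherwise it is approximated as the fraction of scored
#' trials with a non-empty filtered scanpath, and the report says so.
#'
#' @param fix_raw Tagged fixations before filtering (scored trials only).
#' @param fix_filtered Filtered fixations (see [filter_fixations()]).
#' @param scores Optional score tibble (`participant_id` + numeric columns);
#'   when absent the 3-SD rule is skipped.
#' @param keys Item-key tibble used to count scored trials.
#' @param valid_ratio_min Minimum validity ratio.
#' @param min_fix_per_trial Minimum mean raw fixations per trial.
#' @param score_sd_limit SD multiple for the score outlier rule.
#' @param tracking_ratio Optional named numeric vector of recorder tracking
#'   ratios in `[0, 1]`.
#' @return List with `report` (one row per participant: ratios, counts,
#'   `excluded`, `reasons`, `ratio_source`) and `retained` (character vector
#'   of retained participant ids). An empty retained set is an error.
#' @export
qc_participants <- function(fix_raw, fix_filtered, scores = NULL, keys = NULL,
                            valid_ratio_min = 0.5, min_fix_per_trial = 3,
                            score_sd_limit = 3, tracking_ratio = NULL) {
  n_scored <- if (!is.null(keys)) sum(!keys$is_practice) else
    length(unique(fix_raw$trial_id))
  participants <- sort(unique(fix_raw$participant_id))

  raw_counts <- fix_raw |>
    dplyr::count(.data$participant_id, .data$trial_id) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(mean_fix_per_trial = sum(.data$n) / n_scored, .groups = "drop")

  nonempty <- fix_filtered |>
    dplyr::distinct(.data$participant_id, .data$trial_id) |>
    dplyr::count(.data$participant_id, name = "n_nonempty")

  report <- tibble::tibble(participant_id = participants) |>
    dplyr::left_join(raw_counts, by = "participant_id") |>
    dplyr::left_join(nonempty, by = "participant_id") |>
    dplyr::mutate(
      mean_fix_per_trial = dplyr::coalesce(.data$mean_fix_per_trial, 0),
      n_nonempty = dplyr::coalesce(.data$n_nonempty, 0L)
    )

  if (!is.null(tracking_ratio)) {
    report$valid_ratio <- unname(tracking_ratio[report$participant_id])
    report$ratio_source <- "tracking_ratio"
  } else {
    report$valid_ratio <- report$n_nonempty / n_scored
    report$ratio_source <- "fraction_nonempty_trials"
  }

  reasons <- vector("list", nrow(report))
  for (i in seq_len(nrow(report))) {
    r <- character(0)
    if (report$mean_fix_per_trial[i] < min_fix_per_trial) r <- c(r, "low fixation count")
    if (!is.na(report$valid_ratio[i]) && report$valid_ratio[i] < valid_ratio_min) {
      r <- c(r, "low validity ratio")
    }
    reasons[[i]] <- r
  }
  pre_retained <- report$participant_id[lengths(reasons) == 0]

  if (!is.null(scores)) {
    score_cols <- setdiff(names(scores), "participant_id")
    cohort <- scores[scores$participant_id %in% pre_retained, , drop = FALSE]
    for (sc in score_cols) {
      v <- cohort[[sc]]
      m <- mean(v, na.rm = TRUE); s <- sd(v, na.rm = TRUE)
      if (!is.finite(s) || s == 0) next
      out_ids <- cohort$participant_id[!is.na(v) & abs(v - m) > score_sd_limit * s]
      for (pid in out_ids) {
        i <- match(pid, report$participant_id)
        reasons[[i]] <- c(reasons[[i]], sprintf("score outlier (%s)", sc))
      }
    }
  }

  report$excluded <- lengths(reasons) > 0
  report$reasons <- vapply(reasons, function(r)
    if (length(r) == 0) "" else paste(unique(r), collapse = "; "), character(1))
  retained <- report$participant_id[!report$excluded]
  if (length(retained) == 0) {
    abort("quality control excluded every participant", class = "gazestrat_qc_error")
  }
  list(report = report, retained = retained)
}
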