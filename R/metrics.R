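#' Collapse an AOI sequence
#'
#' Merges maximal runs of identical consecutive AOI labels into a single
#' element (consecutive fixations inside one AOI are one "visit"). The
#' operation is idempotent and never lengthens a sequence.
#'
#' @param aoi Character vector of AOI labels in time order.
#' @return Character vector with no two consecutive elements equal.
#' @export
collapse_aoi_sequence <- function(aoi) {
  if (length(aoi) == 0) return(character(0))
  rle(aoi)$values
}

#' Count matrix/answer transition types in a collapsed sequence
#'
#' Classifies every adjacent pair of a collapsed AOI sequence as
#' matrix-to-matrix (`mm`), matrix-answer in either direction (`ma`), or
#' answer-to-answer (`aa`). For a collapsed sequence of length L >= 1,
#' `mm + ma + aa == L - 1`.
#'
#' @param seq Collapsed AOI label vector (matrix and answer labels only).
#' @return Named integer vector `c(mm, ma, aa)`.
#' @export
count_transitions <- function(seq) {
  if (length(seq) < 2) return(c(mm = 0L, ma = 0L, aa = 0L))
  from_m <- is_matrix_aoi(seq[-length(seq)])
  to_m <- is_matrix_aoi(seq[-1])
  c(mm = sum(from_m & to_m),
    ma = sum(xor(from_m, to_m)),
    aa = sum(!from_m & !to_m))
}

#' Names of the fourteen gaze metrics
#'
#' Column names of the participant-level metric table, in canonical order:
#' average item time (s), matrix-matrix / matrix-answer / answer-answer
#' transition totals, latency to the first answer fixation (ms), the
#' matrix/answer dwell-time ratio, mean visits per matrix cell and per
#' incorrect answer choice, fixation counts and mean fixation durations on
#' each side, the percentage of trials classified into cluster 2, and the
#' matrix-answer transition rate per second.
#'
#' @return Character vector of length 14.
#' @export
gaze_metric_names <- function() {
  c("avg_item_time_s", "n_mm_transitions", "n_ma_transitions",
    "n_aa_transitions", "latency_first_answer_ms", "matrix_answer_time_ratio",
    "visits_per_matrix_cell", "visits_per_wrong_answer", "n_fix_matrix",
    "mean_fixdur_matrix_ms", "n_fix_answers", "mean_fixdur_answers_ms",
    "pct_cluster2", "ma_transition_rate_per_s")
}

# per-trial building blocks shared by the participant-level and trial-level
# metric tables; trial_fix must be filtered, tagged and time-ordered.
# Reference single-trial implementation; trial_gaze_metrics() is its
# vectorized whole-table equivalent.
trial_summary_row <- function(trial_fix, correct_choice) {
  seq17 <- collapse_aoi_sequence(trial_fix$aoi)
  tr <- count_transitions(seq17)
  is_m <- trial_fix$aoi_kind == "matrix"
  is_a <- trial_fix$aoi_kind == "answer"
  ans_onsets <- trial_fix$onset_ms[is_a]
  wrong_label <- if (is.na(correct_choice)) NA_character_ else
    sprintf("A_%d", correct_choice)
  visits_answer <- seq17[is_answer_aoi(seq17)]
  tibble::tibble(
    item_time_s = max(trial_fix$onset_ms + trial_fix$duration_ms) / 1000,
    mm = tr[["mm"]], ma = tr[["ma"]], aa = tr[["aa"]],
    latency_ms = if (length(ans_onsets) > 0) min(ans_onsets) else NA_real_,
    dwell_matrix_ms = sum(trial_fix$duration_ms[is_m]),
    dwell_answer_ms = sum(trial_fix$duration_ms[is_a]),
    visits_matrix = sum(is_matrix_aoi(seq17)),
    visits_wrong = if (is.na(wrong_label)) length(visits_answer) else
      sum(visits_answer != wrong_label),
    n_fix_matrix = sum(is_m),
    n_fix_answers = sum(is_a)
  )
}

#' Per-trial gaze summaries
#'
#' One row per non-empty (participant, trial) with the per-trial analogues
#' of the participant metrics: item time, transition counts, latency,
#' dwell totals and the derived per-trial ratios and rates. This table
#' feeds the trial-level cluster contrasts.
#'
#' @param fix Filtered, tagged fixation tibble.
#' @param keys Item-key tibble (used for the correct choice per trial;
#'   practice trials should already have been removed by filtering).
#' @return Tibble with one row per trial.
#' @export
trial_gaze_metrics <- function(fix, keys) {
  key_map <- setNames(keys$correct_choice, keys$trial_id)
  d <- fix[order(fix$participant_id, fix$trial_id, fix$onset_ms,
                 method = "radix"), , drop = FALSE]
  trial_key <- paste(d$participant_id, d$trial_id, sep = "\r")
  new_trial <- !duplicated(trial_key)
  is_m <- d$aoi_kind == "matrix"
  is_a <- d$aoi_kind == "answer"

  # raw-level per-trial aggregates
  raw <- d |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::summarise(
      item_time_s = max(.data$onset_ms + .data$duration_ms) / 1000,
      latency_ms = {
        a <- .data$onset_ms[.data$aoi_kind == "answer"]
        if (length(a) > 0) min(a) else NA_real_
      },
      dwell_matrix_ms = sum(.data$duration_ms[.data$aoi_kind == "matrix"]),
      dwell_answer_ms = sum(.data$duration_ms[.data$aoi_kind == "answer"]),
      n_fix_matrix = sum(.data$aoi_kind == "matrix"),
      n_fix_answers = sum(.data$aoi_kind == "answer"),
      .groups = "drop")

  # collapsed-level aggregates: run starts mark collapsed-sequence elements
  run_start <- new_trial | d$aoi != dplyr::lag(d$aoi, default = "")
  cd <- d[run_start, c("participant_id", "trial_id", "aoi"), drop = FALSE]
  cd_new <- new_trial[run_start]
  prev_m <- dplyr::lag(is_matrix_aoi(cd$aoi), default = FALSE)
  cur_m <- is_matrix_aoi(cd$aoi)
  pair <- !cd_new                      # rows with a predecessor in the same trial
  cd$mm <- pair & prev_m & cur_m
  cd$ma <- pair & xor(prev_m, cur_m)
  cd$aa <- pair & !prev_m & !cur_m
  cd$is_visit_m <- cur_m
  wrong_of <- sprintf("A_%d", key_map[cd$trial_id])
  cd$is_visit_wrong <- is_answer_aoi(cd$aoi) & cd$aoi != wrong_of
  coll <- cd |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::summarise(
      mm = sum(.data$mm), ma = sum(.data$ma), aa = sum(.data$aa),
      visits_matrix = sum(.data$is_visit_m),
      visits_wrong = sum(.data$is_visit_wrong),
      .groups = "drop")

  out <- dplyr::inner_join(raw, coll, by = c("participant_id", "trial_id"))
  out <- out[, c("participant_id", "trial_id", "item_time_s", "mm", "ma", "aa",
                 "latency_ms", "dwell_matrix_ms", "dwell_answer_ms",
                 "visits_matrix", "visits_wrong", "n_fix_matrix",
                 "n_fix_answers")]
  out |>
    dplyr::mutate(
      matrix_answer_time_ratio = ifelse(.data$dwell_answer_ms > 0,
                                        .data$dwell_matrix_ms / .data$dwell_answer_ms,
                                        NA_real_),
      visits_per_matrix_cell = .data$visits_matrix / 9,
      visits_per_wrong_answer = .data$visits_wrong / 7,
      mean_fixdur_matrix_ms = ifelse(.data$n_fix_matrix > 0,
                                     .data$dwell_matrix_ms / .data$n_fix_matrix,
                                     NA_real_),
      mean_fixdur_answers_ms = ifelse(.data$n_fix_answers > 0,
                                      .data$dwell_answer_ms / .data$n_fix_answers,
                                      NA_real_),
      ma_transition_rate_per_s = .data$ma / .data$item_time_s
    )
}

#' Participant-level gaze metrics
#'
#' Computes the fourteen gaze metrics for every participant from filtered
#' trial scanpaths. Aggregation follows the totals convention: transition
#' and fixation counts are totals over the scored trials; time-type metrics
#' are per-trial (or per-fixation) means; visit metrics are means per cell
#' (or per incorrect choice) per trial; the dwell ratio is total matrix
#' dwell over total answer dwell; and the matrix-answer transition rate is
#' the transition total divided by total trial time, which makes
#' `ma_transition_rate_per_s * avg_item_time_s * n_trials ==
#' n_ma_transitions` an exact identity.
#'
#' Degenerate denominators yield `NA`, never infinities: a participant who
#' never fixates an answer AOI has `NA` latency, ratio and answer-side
#' duration metrics. `pct_cluster2` is `NA` unless cluster labels are
#' supplied.
#'
#' @param fix Filtered, tagged fixation tibble (practice trials removed).
#' @param keys Item-key tibble.
#' @param cluster_labels Optional tibble (`participant_id`, `trial_id`,
#'   `label` in 1/2) from [fit_two_cluster_model()].
#' @return Tibble: `participant_id`, `n_trials`, the 14 metric columns,
#'   and `n_missing` (count of NA metrics per participant).
#' @export
compute_gaze_metrics <- function(fix, keys, cluster_labels = NULL) {
  if (nrow(fix) == 0) {
    abort("no fixations left to compute metrics from", class = "gazestrat_metric_error")
  }
  per_trial <- trial_gaze_metrics(fix, keys)
  agg <- per_trial |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      avg_item_time_s = mean(.data$item_time_s),
      n_mm_transitions = sum(.data$mm),
      n_ma_transitions = sum(.data$ma),
      n_aa_transitions = sum(.data$aa),
      latency_first_answer_ms = if (all(is.na(.data$latency_ms))) NA_real_ else
        mean(.data$latency_ms, na.rm = TRUE),
      dwell_matrix_ms = sum(.data$dwell_matrix_ms),
      dwell_answer_ms = sum(.data$dwell_answer_ms),
      visits_matrix = sum(.data$visits_matrix),
      visits_wrong = sum(.data$visits_wrong),
      n_fix_matrix = sum(.data$n_fix_matrix),
      n_fix_answers = sum(.data$n_fix_answers),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      matrix_answer_time_ratio = ifelse(.data$dwell_answer_ms > 0,
                                        .data$dwell_matrix_ms / .data$dwell_answer_ms,
                                        NA_real_),
      visits_per_matrix_cell = .data$visits_matrix / (9 * .data$n_trials),
      visits_per_wrong_answer = .data$visits_wrong / (7 * .data$n_trials),
      mean_fixdur_matrix_ms = ifelse(.data$n_fix_matrix > 0,
                                     .data$dwell_matrix_ms / .data$n_fix_matrix,
                                     NA_real_),
      mean_fixdur_answers_ms = ifelse(.data$n_fix_answers > 0,
                                      .data$dwell_answer_ms / .data$n_fix_answers,
                                      NA_real_),
      ma_transition_rate_per_s =
        .data$n_ma_transitions / (.data$avg_item_time_s * .data$n_trials)
    )

  if (!is.null(cluster_labels)) {
    pct <- cluster_labels |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(pct_cluster2 = percent_cluster2(.data$label), .groups = "drop")
    agg <- dplyr::left_join(agg, pct, by = "participant_id")
  } else {
    agg$pct_cluster2 <- NA_real_
  }

  out <- agg[, c("participant_id", "n_trials", gaze_metric_names())]
  out$n_missing <- rowSums(is.na(out[, gaze_metric_names()]))
  out
}
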