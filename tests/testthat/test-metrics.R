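test_that("collapsing merges runs and is idempotent", {
  expect_equal(collapse_aoi_sequence(c("M_0_0", "M_0_0", "A_2", "A_2", "M_1_1")),
               c("M_0_0", "A_2", "M_1_1"))
  expect_equal(collapse_aoi_sequence(rep("A_5", 7)), "A_5")
  expect_equal(collapse_aoi_sequence(character(0)), character(0))
  withr::local_seed(1)
  for (i in 1:20) {
    s <- random_collapsed_seq(50)
    expect_identical(collapse_aoi_sequence(s), s)
    expect_lte(length(s), 50)
  }
})

test_that("transition counts partition adjacent pairs", {
  expect_equal(count_transitions(c("M_0_0", "M_0_1", "A_0", "A_1", "M_2_2")),
               c(mm = 1L, ma = 2L, aa = 1L))
  expect_equal(count_transitions("M_1_1"), c(mm = 0L, ma = 0L, aa = 0L))
  # brute-force pairwise count over random 200-element sequences
  withr::local_seed(2)
  for (i in 1:50) {
    s <- random_collapsed_seq(400)   # collapses to <= 400
    tr <- count_transitions(s)
    brute <- table(factor(paste0(
      ifelse(startsWith(head(s, -1), "M"), "m", "a"),
      ifelse(startsWith(s[-1], "M"), "m", "a")),
      levels = c("mm", "ma", "am", "aa")))
    expect_equal(unname(tr[["mm"]]), unname(brute[["mm"]]))
    expect_equal(unname(tr[["ma"]]), unname(brute[["ma"]] + brute[["am"]]))
    expect_equal(unname(tr[["aa"]]), unname(brute[["aa"]]))
    expect_equal(sum(tr), length(s) - 1L)
  }
})

# two hand-constructed trials; every expected value below is recomputed by
# hand from the retained fixations (first fixation, sub-100 ms and outside
# events are dropped by the filters)
test_that("the fourteen participant metrics match a hand computation", {
  rows <- list(
    # trial T01 (correct choice 3)
    list("T01", 0, 150, "M_0_0"),    # first: dropped
    list("T01", 200, 120, "M_0_0"),
    list("T01", 350, 90, "M_0_1"),   # sub-threshold: dropped
    list("T01", 460, 150, "M_0_1"),
    list("T01", 630, 200, "OUT"),    # outside: dropped
    list("T01", 850, 250, "A_2"),
    list("T01", 1120, 130, "A_2"),
    list("T01", 1270, 180, "M_2_2"),
    # trial T02 (correct choice 5)
    list("T02", 0, 200, "M_1_1"),    # first: dropped
    list("T02", 250, 300, "M_1_0"),
    list("T02", 600, 100, "A_5"),    # exactly 100 ms: retained
    list("T02", 720, 140, "A_4"),
    list("T02", 880, 160, "A_4"),
    list("T02", 1060, 220, "M_1_0"))
  bundle <- bundled_layout()
  tagged <- tag_fixations(make_fixations(rows), bundle$layout)
  filtered <- filter_fixations(tagged, bundle$keys)
  labels <- tibble::tibble(participant_id = "P1", trial_id = c("T01", "T02"),
                           label = c(1L, 2L))
  m <- compute_gaze_metrics(filtered, bundle$keys, cluster_labels = labels)

  expect_equal(m$n_trials, 2L)
  # T01 retained: [M00 120, M01 150, A2 250, A2 130, M22 180]
  # T02 retained: [M10 300, A5 100, A4 140, A4 160, M10 220]
  expect_equal(m$avg_item_time_s, (1.45 + 1.28) / 2)
  expect_equal(m$n_mm_transitions, 1L)          # M00->M01
  expect_equal(m$n_ma_transitions, 4L)          # M01->A2, A2->M22, M10->A5, A4->M10
  expect_equal(m$n_aa_transitions, 1L)          # A5->A4
  expect_equal(m$latency_first_answer_ms, (850 + 600) / 2)
  expect_equal(m$matrix_answer_time_ratio, 970 / 780)
  expect_equal(m$visits_per_matrix_cell, 5 / 18)
  expect_equal(m$visits_per_wrong_answer, 2 / 14)  # A2 (T01), A4 (T02)
  expect_equal(m$n_fix_matrix, 5L)
  expect_equal(m$mean_fixdur_matrix_ms, 970 / 5)
  expect_equal(m$n_fix_answers, 5L)
  expect_equal(m$mean_fixdur_answers_ms, 780 / 5)
  expect_equal(m$pct_cluster2, 50)
  expect_equal(m$ma_transition_rate_per_s, 4 / (m$avg_item_time_s * 2))
  expect_equal(m$n_missing, 0)
})

test_that("degenerate participants get NA metrics, never infinities", {
  rows <- list(list("T01", 0, 150, "M_0_0"),
               list("T01", 200, 150, "M_0_1"),
               list("T01", 400, 150, "M_0_2"))
  bundle <- bundled_layout()
  filtered <- filter_fixations(tag_fixations(make_fixations(rows), bundle$layout),
                               bundle$keys)
  m <- compute_gaze_metrics(filtered, bundle$keys)
  expect_true(is.na(m$latency_first_answer_ms))
  expect_true(is.na(m$matrix_answer_time_ratio))
  expect_true(is.na(m$mean_fixdur_answers_ms))
  expect_equal(m$n_fix_answers, 0L)
  expect_true(all(is.finite(unlist(m[gaze_metric_names()])) |
                    is.na(unlist(m[gaze_metric_names()]))))
  expect_error(compute_gaze_metrics(filtered[0, ], bundle$keys),
               class = "gazestrat_metric_error")
})

test_that("metrics are invariant to trial order and satisfy the rate identity", {
  withr::local_seed(3)
  st <- simulate_study(small_config())
  bundle <- list(layout = st$layout, keys = st$keys)
  filtered <- filter_fixations(tag_fixations(st$fixations, st$layout), st$keys)
  m1 <- compute_gaze_metrics(filtered, st$keys)
  m2 <- compute_gaze_metrics(filtered[sample(nrow(filtered)), ], st$keys)
  expect_equal(m1, m2)
  # metric-14 identity under the totals convention
  expect_equal(m1$ma_transition_rate_per_s * m1$avg_item_time_s * m1$n_trials,
               as.numeric(m1$n_ma_transitions), tolerance = 1e-9)
})

test_that("strategy kernels shift toggle counts and dwell ratio oppositely", {
  # pure constructive vs pure hybrid cohorts
  st_c <- simulate_study(small_config(seed = 5, propensity_shape = c(0.1, 100)))
  st_h <- simulate_study(small_config(seed = 5, propensity_shape = c(100, 0.1)))
  mc <- st_c$truth$metrics
  mh <- st_h$truth$metrics
  expect_gt(mean(mh$n_ma_transitions), mean(mc$n_ma_transitions))
  expect_lt(mean(mh$matrix_answer_time_ratio), mean(mc$matrix_answer_time_ratio))
})
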