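test_that("AOI tagging is a pure function of coordinates with half-open rects", {
  layout <- bundled_layout()$layout
  cell <- layout$matrix_cells[layout$matrix_cells$label == "M_0_0", ]
  fix <- tibble::tibble(
    participant_id = "P1", trial_id = "T01", trial_index = 4,
    onset_ms = c(0, 100, 200, 300),
    duration_ms = 100,
    x_px = c(mean(c(cell$x0, cell$x1)), 10, cell$x1, cell$x0),
    y_px = c(mean(c(cell$y0, cell$y1)), 10, cell$y0, cell$y0))
  tagged <- tag_fixations(fix, layout)
  expect_equal(tagged$aoi[1], "M_0_0")             # centre
  expect_equal(tagged$aoi[2], "OUT")               # margin
  # right edge is exclusive: the point belongs to the gap (OUT here)
  expect_equal(tagged$aoi[3], "OUT")
  # left edge is inclusive
  expect_equal(tagged$aoi[4], "M_0_0")
})

test_that("trial filtering applies the drop-first, outside and duration rules", {
  rows <- list(
    list("T01", 0, 120, "M_0_0"),     # first raw fixation: always dropped
    list("T01", 150, 90, "M_0_1"),    # under 100 ms
    list("T01", 260, 150, "M_0_2"),
    list("T01", 430, 200, "M_1_0"))
  tagged <- tag_fixations(make_fixations(rows), bundled_layout()$layout)
  kept <- filter_trial(tagged)
  expect_equal(kept$duration_ms, c(150, 200))

  # strict rule drops a boundary 100 ms event, inclusive keeps it
  rows2 <- list(list("T01", 0, 500, "M_0_0"), list("T01", 600, 100, "M_0_1"))
  tagged2 <- tag_fixations(make_fixations(rows2), bundled_layout()$layout)
  expect_equal(nrow(filter_trial(tagged2)), 1)
  expect_equal(nrow(filter_trial(tagged2, strict = TRUE)), 0)

  # all fixations outside -> empty scanpath, not an error
  rows3 <- list(list("T01", 0, 150, "OUT"), list("T01", 200, 150, "OUT"))
  tagged3 <- tag_fixations(make_fixations(rows3), bundled_layout()$layout)
  expect_equal(nrow(filter_trial(tagged3)), 0)

  # n in-AOI fixations all >= 100 ms -> n - 1 retained
  rows4 <- lapply(0:4, function(i) list("T01", i * 200, 150, "M_1_1"))
  tagged4 <- tag_fixations(make_fixations(rows4), bundled_layout()$layout)
  expect_equal(nrow(filter_trial(tagged4)), 4)
})

test_that("filtering is idempotent and dwell never exceeds raw trial time", {
  withr::local_seed(42)
  st <- simulate_study(small_config())
  tagged <- tag_fixations(st$fixations, st$layout)
  f1 <- filter_fixations(tagged, st$keys)
  f2 <- filter_fixations(f1, st$keys, drop_first = FALSE)
  expect_equal(f2, f1)

  raw_time <- tagged |>
    dplyr::group_by(participant_id, trial_id) |>
    dplyr::summarise(raw = max(onset_ms + duration_ms), .groups = "drop")
  dwell <- f1 |>
    dplyr::group_by(participant_id, trial_id) |>
    dplyr::summarise(dwell = sum(duration_ms), .groups = "drop") |>
    dplyr::inner_join(raw_time, by = c("participant_id", "trial_id"))
  expect_true(all(dwell$dwell <= dwell$raw + 1e-9))
  # vectorized filter agrees with the single-trial reference
  one <- tagged[tagged$participant_id == "S001" & tagged$trial_id == "T05", ]
  expect_equal(
    filter_trial(one)$onset_ms,
    f1$onset_ms[f1$participant_id == "S001" & f1$trial_id == "T05"])
})

test_that("participant QC fires the fixation-count, ratio and outlier rules", {
  keys <- bundled_layout()$keys
  layout <- bundled_layout()$layout
  scored <- keys$trial_id[!keys$is_practice]
  # P_low: 2 fixations per trial; P_ok/P_out: 12 per trial
  mk <- function(pid, per_trial) {
    rows <- unlist(lapply(scored, function(tid) {
      lapply(seq_len(per_trial), function(i)
        list(tid, (i - 1) * 200, 150, if (i %% 3 == 0) "A_1" else "M_1_1"))
    }), recursive = FALSE)
    make_fixations(rows, participant = pid)
  }
  raw <- tag_fixations(dplyr::bind_rows(mk("P_low", 2), mk("P_ok", 12),
                                        mk("P_out", 12)), layout)
  filt <- filter_fixations(raw, keys)
  scores <- tibble::tibble(participant_id = c("P_low", "P_ok", "P_out"),
                           planning = c(50, 52, 51))
  qc <- qc_participants(raw, filt, scores, keys)
  expect_setequal(qc$retained, c("P_ok", "P_out"))
  expect_match(qc$report$reasons[qc$report$participant_id == "P_low"],
               "low fixation count")

  # validity-ratio threshold boundary via supplied tracking ratios
  qc2 <- qc_participants(raw, filt, scores, keys,
                         tracking_ratio = c(P_low = 0.9, P_ok = 0.49, P_out = 0.5))
  expect_false("P_ok" %in% qc2$retained)
  expect_true("P_out" %in% qc2$retained)

  # a genuine 3-SD outlier is excluded; identical scores exclude nobody
  scores3 <- tibble::tibble(participant_id = c("P_low", "P_ok", "P_out"),
                            planning = c(50, 52, 51), wm = c(10, 10, 10))
  many <- dplyr::bind_rows(lapply(sprintf("Q%02d", 1:12), mk, per_trial = 8))
  raw_many <- tag_fixations(many, layout)
  filt_many <- filter_fixations(raw_many, keys)
  sc <- tibble::tibble(participant_id = sprintf("Q%02d", 1:12),
                       planning = c(rep(50, 11), 5000), wm = 7)
  qc3 <- qc_participants(raw_many, filt_many, sc, keys)
  expect_false("Q12" %in% qc3$retained)
  expect_match(qc3$report$reasons[qc3$report$participant_id == "Q12"],
               "score outlier")
  expect_equal(sum(qc3$report$excluded), 1)        # wm constant: no exclusions

  # QC decisions are invariant to participant order
  qc4 <- qc_participants(raw_many[sample(nrow(raw_many)), ], filt_many, sc, keys)
  expect_setequal(qc4$retained, qc3$retained)
})
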