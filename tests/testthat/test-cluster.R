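test_that("transition features are row-normalized counts with zero diagonal", {
  f <- build_transition_features(c("M_0_0", "M_0_1", "M_0_2", "A_3"))
  expect_equal(f$P["M_0_0", "M_0_1"], 1)
  expect_equal(f$P["M_0_1", "M_0_2"], 1)
  expect_equal(f$P["M_0_2", "ANS"], 1)
  expect_equal(sum(f$P), 3)                       # all other rows zero
  expect_false(f$degenerate)

  f2 <- build_transition_features(c("M_0_0", "A_1", "M_0_0", "A_5"))
  expect_equal(f2$P["M_0_0", "ANS"], 1)
  expect_equal(f2$P["ANS", "M_0_0"], 1)

  # consecutive answer choices pool into one ANS element
  f3 <- build_transition_features(c("A_0", "A_5", "M_1_1"))
  expect_equal(f3$P["ANS", "M_1_1"], 1)
  expect_equal(sum(f3$P), 1)

  expect_true(build_transition_features("M_0_0")$degenerate)
  expect_equal(sum(build_transition_features("M_0_0")$features), 0)

  withr::local_seed(4)
  for (i in 1:300) {
    P <- build_transition_features(random_collapsed_seq(sample(2:60, 1)))$P
    rs <- rowSums(P)
    expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
    expect_true(all(diag(P) == 0))
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("the vectorized feature table matches the per-trial builder", {
  withr::local_seed(5)
  st <- simulate_study(small_config())
  filtered <- filter_fixations(tag_fixations(st$fixations, st$layout), st$keys)
  ft <- transition_feature_table(filtered)
  one <- filtered[filtered$participant_id == ft$trials$participant_id[13] &
                    filtered$trial_id == ft$trials$trial_id[13], ]
  one <- one[order(one$onset_ms), ]
  ref <- build_transition_features(collapse_aoi_sequence(one$aoi))
  expect_equal(unname(ft$X[13, ]), unname(ref$features))
  expect_equal(colnames(ft$X), names(ref$features))
})

test_that("two-centroid fits reach the exhaustive optimum and orient canonically", {
  withr::local_seed(6)
  # well-separated groups differing in answer-entry mass
  base1 <- c(rep(0.9, 3), rep(0.01, 87))
  base2 <- c(rep(0.05, 3), rep(0.8, 87)) / 10
  names(base1) <- names(base2) <- gazestrat:::transition_feature_names()
  ans_idx <- gazestrat:::answer_entry_feature_idx()
  base2[ans_idx] <- 0.4                            # group 2 enters answers more
  X <- rbind(t(replicate(4, base1 + runif(90, 0, 0.02))),
             t(replicate(4, base2 + runif(90, 0, 0.02))))
  fit <- fit_two_cluster_model(X, seed = 1)
  expect_equal(fit$objective, exhaustive_two_cluster_sse(X), tolerance = 1e-9)
  expect_equal(fit$labels, rep(c(1L, 2L), each = 4))   # canonical orientation

  # random small fixtures also reach the global optimum
  for (i in 1:6) {
    Xr <- matrix(runif(7 * 90), 7, 90)
    fitr <- fit_two_cluster_model(Xr, seed = i)
    expect_equal(fitr$objective, exhaustive_two_cluster_sse(Xr), tolerance = 1e-9)
  }

  # duplication invariance of the SSE minimizer
  fit2 <- fit_two_cluster_model(rbind(X, X), seed = 3)
  expect_equal(sort(fit2$centroids[1, ]), sort(fit$centroids[1, ]),
               tolerance = 1e-9)

  # determinism under a fixed seed
  fit3 <- fit_two_cluster_model(X, seed = 1)
  expect_identical(fit3$labels, fit$labels)
  expect_identical(fit3$objective, fit$objective)

  # all-identical vectors -> degenerate single cluster with a warning
  expect_warning(fitd <- fit_two_cluster_model(X[c(1, 1, 1), ] * 0 + 1, seed = 1),
                 "identical")
  expect_true(all(fitd$labels == 1L))

  # centroid matrices reshape back with zero diagonal
  cm <- centroid_matrix(fit, 2)
  expect_equal(diag(cm), rep(0, 10), ignore_attr = TRUE)
  expect_gt(sum(cm[1:9, "ANS"]), sum(centroid_matrix(fit, 1)[1:9, "ANS"]))
})

test_that("cluster-2 percentages are complements of cluster-1 percentages", {
  expect_equal(percent_cluster2(c(2L, 2L, 1L, 1L)), 50)
  expect_equal(percent_cluster2(rep(1L, 6)), 0)
  withr::local_seed(7)
  for (i in 1:100) {
    lab <- sample(1:2, sample(1:30, 1), replace = TRUE)
    expect_identical(percent_cluster1(lab) + percent_cluster2(lab), 100)
  }
  expect_error(percent_cluster2(integer(0)), class = "gazestrat_cluster_error")
})

test_that("JZS Bayes factors agree with an independent quadrature oracle", {
  skip_if_not_installed("pracma")
  for (t in c(0, 0.8, 2.5, 4)) {
    for (n in c(20, 200)) {
      expect_equal(jzs_bf10_from_t(t, n, n), jzs_bf10_oracle(t, n, n),
                   tolerance = 1e-6)
    }
  }
})

test_that("cluster contrasts produce calibrated Bayes-factor evidence", {
  withr::local_seed(8)
  # identically distributed groups: moderate evidence for H0
  x <- rnorm(500); y <- rnorm(500)
  res0 <- compare_clusters_bf(c(x, y), rep(1:2, each = 500))
  expect_lt(res0$bf10, 1 / 3)
  expect_match(res0$category, "H0")

  # standardized mean difference 1.5: overwhelming evidence for H1
  y2 <- rnorm(200) + 1.5
  res1 <- compare_clusters_bf(c(rnorm(200), y2), rep(1:2, each = 200))
  expect_gt(res1$bf10, 100)
  expect_match(res1$category, "extreme")

  expect_error(compare_clusters_bf(c(1, 2, 3), c(1L, 1L, 2L)),
               class = "gazestrat_bf_error")
})

test_that("the cluster contrast table covers all trial-level metrics", {
  withr::local_seed(9)
  st <- simulate_study(small_config())
  filtered <- filter_fixations(tag_fixations(st$fixations, st$layout), st$keys)
  ft <- transition_feature_table(filtered)
  fit <- fit_two_cluster_model(ft$X, seed = 2)
  per_trial <- trial_gaze_metrics(filtered, st$keys)
  bf <- cluster_bf_table(per_trial, fit, ft$trials)
  expect_equal(nrow(bf), 13)
  expect_true(all(bf$bf10 > 0))
  expect_equal(bf$bf10 * bf$bf01, rep(1, 13))
})
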