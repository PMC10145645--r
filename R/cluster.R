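#' Pool answer choices and re-collapse an AOI sequence
#'
#' Maps the eight answer-choice labels to the single pooled answer region
#' `ANS` and collapses runs again, giving the 10-AOI representation (nine
#' matrix cells + one answer region) used by the scanpath clustering.
#'
#' @param seq Collapsed 17-AOI label vector.
#' @return Collapsed 10-AOI label vector.
#' @export
pool_answer_aois <- function(seq) {
  seq[is_answer_aoi(seq)] <- "ANS"
  collapse_aoi_sequence(seq)
}

#' Transition-matrix features of one scanpath
#'
#' Counts the AOI-to-AOI moves of a collapsed 10-AOI sequence and
#' row-normalizes them into a transition probability matrix. Rows with no
#' outgoing move stay all-zero (a uniform row would fabricate transitions
#' never observed); the diagonal is identically zero because the sequence
#' is collapsed. The feature vector is the flattened 90-element off-diagonal.
#'
#' @param seq Collapsed AOI label vector (17- or 10-AOI; answers are pooled
#'   internally).
#' @return List with `P` (10x10 row-stochastic-or-zero matrix), `features`
#'   (named numeric, length 90), and `degenerate` (`TRUE` when the sequence
#'   has fewer than two elements).
#' @export
build_transition_features <- function(seq) {
  labs <- aoi10_labels()
  seq <- pool_answer_aois(seq)
  P <- matrix(0, 10, 10, dimnames = list(labs, labs))
  degenerate <- length(seq) < 2
  if (!degenerate) {
    from <- factor(seq[-length(seq)], levels = labs)
    to <- factor(seq[-1], levels = labs)
    counts <- table(from, to)
    P[] <- as.numeric(counts)
    rs <- rowSums(P)
    nz <- rs > 0
    P[nz, ] <- P[nz, , drop = FALSE] / rs[nz]
  }
  features <- as.vector(t(P))[off_diag_rowmajor()]
  names(features) <- transition_feature_names()
  list(P = P, features = features, degenerate = degenerate)
}

# off-diagonal cells in from-major (row-major) order, shared by every
# producer/consumer of the 90-element feature vector
off_diag_rowmajor <- function() as.vector(t(!diag(10)))

transition_feature_names <- function() {
  labs <- aoi10_labels()
  as.vector(t(outer(labs, labs, function(a, b) paste(a, b, sep = "->"))))[
    off_diag_rowmajor()]
}

#' Transition features for every trial
#'
#' @param fix Filtered, tagged fixation tibble.
#' @return List with `X` (trials x 90 feature matrix), `trials` (tibble of
#'   participant/trial ids in row order), `degenerate` (logical per trial).
#' @export
transition_feature_table <- function(fix) {
  labs <- aoi10_labels()
  d <- fix[order(fix$participant_id, fix$trial_id, fix$onset_ms,
                 method = "radix"), , drop = FALSE]
  trial_key <- paste(d$participant_id, d$trial_id, sep = "\r")
  new_trial <- !duplicated(trial_key)
  trials <- tibble::tibble(participant_id = d$participant_id[new_trial],
                           trial_id = d$trial_id[new_trial])
  tix <- cumsum(new_trial)
  aoi10 <- ifelse(is_answer_aoi(d$aoi), "ANS", d$aoi)
  # collapse at the pooled 10-AOI level, then count i->j moves per trial
  run_start <- new_trial | aoi10 != dplyr::lag(aoi10, default = "")
  s10 <- match(aoi10[run_start], labs)
  st <- tix[run_start]
  snew <- new_trial[run_start]
  from <- s10[-length(s10)]; to <- s10[-1]
  keep <- !snew[-1]                      # moves within one trial only
  cell <- (st[-1][keep] - 1L) * 100L + (from[keep] - 1L) * 10L + to[keep]
  counts <- matrix(tabulate(cell, nbins = nrow(trials) * 100L),
                   nrow = nrow(trials), ncol = 100L, byrow = TRUE)
  # row-normalize each trial's 10x10 block
  P <- counts
  for (r in 1:10) {
    block <- P[, ((r - 1) * 10 + 1):(r * 10), drop = FALSE]
    rs <- rowSums(block)
    nz <- rs > 0
    block[nz, ] <- block[nz, , drop = FALSE] / rs[nz]
    P[, ((r - 1) * 10 + 1):(r * 10)] <- block
  }
  X <- P[, off_diag_rowmajor(), drop = FALSE]
  colnames(X) <- transition_feature_names()
  degenerate <- rowSums(counts) == 0
  list(X = X, trials = trials, degenerate = degenerate)
}

exact_two_cluster <- function(X) {
  n <- nrow(X)
  best <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    c1 <- colMeans(X[grp, , drop = FALSE])
    c2 <- colMeans(X[!grp, , drop = FALSE])
    sse <- sum(sweep(X[grp, , drop = FALSE], 2, c1)^2) +
      sum(sweep(X[!grp, , drop = FALSE], 2, c2)^2)
    if (is.null(best) || sse < best$objective - 1e-12) {
      best <- list(centers = rbind(c1, c2),
                   labels = ifelse(grp, 1L, 2L), objective = sse)
    }
  }
  best
}

# indices of the features that flow into the pooled answer region; their
# centroid mass defines the canonical cluster orientation
answer_entry_feature_idx <- function() {
  grep("->ANS$", transition_feature_names())
}

#' Fit the two-cluster scanpath model
#'
#' Standard k-means (within-cluster sum of squared Euclidean distances)
#' with k = 2 on the trials' transition features. Initialization is a
#' seeded farthest-point rule: each restart picks a random trial as the
#' first center and the trial farthest from it as the second, then runs
#' Lloyd iterations; the restart with the lowest objective wins, ties going
#' to the earliest restart. For 12 or fewer scanpaths the objective is
#' minimized exactly by enumerating all bipartitions instead. Labels are canonically oriented: cluster 2 is
#' the cluster whose centroid carries the larger total transition mass
#' into the answer region (the hybrid, answer-oriented strategy), so the
#' labeling is stable across seeds on separable data.
#'
#' @param X Trials x 90 feature matrix (see [transition_feature_table()]).
#' @param seed Integer seed controlling all restarts.
#' @param restarts Number of seeded initializations.
#' @return Object of class `scanpath_clusters`: `centroids` (2 x 90),
#'   `labels` (1/2 per row of `X`), `objective` (within-cluster SSE),
#'   `seed`, `restarts`, `degenerate`.
#' @export
fit_two_cluster_model <- function(X, seed = 1L, restarts = 25L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2) abort("need at least 2 scanpaths to cluster", class = "gazestrat_cluster_error")
  distinct <- nrow(unique(X))
  if (distinct < 2) {
    warn("all transition-feature vectors are identical; degenerate one-cluster model")
    fit <- structure(list(centroids = rbind(X[1, ], X[1, ]),
                          labels = rep(1L, n), objective = 0,
                          seed = seed, restarts = restarts, degenerate = TRUE),
                     class = "scanpath_clusters")
    return(fit)
  }
  if (n <= 12) {
    # tiny inputs: the k = 2 objective is minimized exactly by enumerating
    # all non-empty bipartitions (Lloyd restarts can miss the global
    # optimum on unstructured points)
    ex <- exact_two_cluster(X)
    best <- list(centers = ex$centers, cluster = ex$labels,
                 tot.withinss = ex$objective)
  } else {
  best <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      i1 <- sample.int(n, 1)
      d2 <- rowSums(sweep(X, 2, X[i1, ])^2)
      i2 <- which.max(d2)
      if (d2[i2] == 0) next
      km <- tryCatch(
        kmeans(X, centers = X[c(i1, i2), , drop = FALSE], iter.max = 100,
               algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(kmeans(X, centers = X[c(i1, i2), , drop = FALSE],
                                  iter.max = 100, algorithm = "Lloyd"))
        })
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss - 1e-12) best <- km
    }
    best
  })
  }
  if (is.null(best)) abort("clustering failed in every restart",
                           class = "gazestrat_cluster_error")

  ans_idx <- answer_entry_feature_idx()
  mass <- rowSums(best$centers[, ans_idx, drop = FALSE])
  labels <- best$cluster
  if (mass[1] > mass[2]) {           # cluster with larger answer mass becomes 2
    labels <- 3L - labels
    best$centers <- best$centers[2:1, , drop = FALSE]
  }
  structure(list(centroids = best$centers, labels = as.integer(labels),
                 objective = best$tot.withinss, seed = seed,
                 restarts = restarts, degenerate = FALSE),
            class = "scanpath_clusters")
}

#' @export
print.scanpath_clusters <- function(x, ...) {
  cat(sprintf("<scanpath_clusters> %d trials, objective %.4f, sizes %s\n",
              length(x$labels), x$objective,
              paste(table(factor(x$labels, levels = 1:2)), collapse = "/")))
  invisible(x)
}

#' Reshape a centroid row back into its 10x10 transition matrix
#'
#' @param fit A `scanpath_clusters` object.
#' @param cluster 1 or 2.
#' @return 10x10 matrix with zero diagonal.
#' @export
centroid_matrix <- function(fit, cluster) {
  labs <- aoi10_labels()
  tP <- matrix(0, 10, 10)
  tP[t(!diag(10))] <- fit$centroids[cluster, ]   # row-major feature order
  P <- t(tP)
  dimnames(P) <- list(labs, labs)
  P
}

#' Percentage of trials classified as cluster 2
#'
#' The complementary percentage for cluster 1 satisfies
#' `pct_cluster1 + pct_cluster2 == 100` exactly.
#'
#' @param labels Integer vector of 1/2 trial labels.
#' @return Percentage in `[0, 100]`.
#' @export
percent_cluster2 <- function(labels) {
  if (length(labels) == 0) abort("no labels", class = "gazestrat_cluster_error")
  100 * mean(labels == 2L)
}

#' @rdname percent_cluster2
#' @export
percent_cluster1 <- function(labels) 100 - percent_cluster2(labels)

#' Bayes-factor contrast of the two clusters on one metric
#'
#' Two-sample Jeffreys-Zellner-Siow Bayes factor (Cauchy prior on the
#' standardized effect, scale `sqrt(2)/2`) comparing the trial-level values
#' of a gaze metric between the two scanpath clusters. `BF10` quantifies
#' evidence for a cluster difference; `BF01 = 1/BF10`. The evidence
#' category follows the usual thresholds (3, 10, 100 and reciprocals).
#'
#' @param values Numeric metric values, one per trial.
#' @param labels Cluster labels (1/2) aligned with `values`.
#' @param rscale Cauchy prior scale.
#' @return One-row tibble: group means/SDs/sizes, `bf10`, `bf01`, `category`.
#' @export
compare_clusters_bf <- function(values, labels, rscale = sqrt(2) / 2) {
  keep <- !is.na(values)
  values <- values[keep]; labels <- labels[keep]
  x <- values[labels == 1L]; y <- values[labels == 2L]
  if (length(x) < 2 || length(y) < 2) {
    abort("each cluster needs at least 2 values for a Bayes-factor contrast",
          class = "gazestrat_bf_error")
  }
  bf <- jzs_bf10(x, y, rscale = rscale)
  tibble::tibble(
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), mean2 = mean(y), sd1 = sd(x), sd2 = sd(y),
    bf10 = bf, bf01 = 1 / bf, category = bf_category(bf)
  )
}

bf_category <- function(bf) {
  stopifnot(bf > 0)
  if (bf > 100) "extreme evidence for H1"
  else if (bf > 10) "strong evidence for H1"
  else if (bf > 3) "moderate evidence for H1"
  else if (bf >= 1 / 3) "anecdotal"
  else if (bf >= 1 / 10) "moderate evidence for H0"
  else if (bf >= 1 / 100) "strong evidence for H0"
  else "extreme evidence for H0"
}

#' Cluster contrasts over all trial-level gaze metrics
#'
#' Runs [compare_clusters_bf()] for each per-trial metric column (the
#' thirteen trial-level analogues of the participant metrics; the cluster-2
#' percentage is participant-level and has no trial-level contrast).
#'
#' @param per_trial Output of [trial_gaze_metrics()].
#' @param fit A `scanpath_clusters` whose labels align with
#'   `transition_feature_table()` row order on the same fixations.
#' @param trials The `trials` tibble from [transition_feature_table()].
#' @return Tibble, one row per metric, with direction of the difference.
#' @export
cluster_bf_table <- function(per_trial, fit, trials) {
  labeled <- dplyr::left_join(
    per_trial,
    dplyr::mutate(trials, label = fit$labels),
    by = c("participant_id", "trial_id")
  )
  metrics <- c("item_time_s", "mm", "ma", "aa", "latency_ms",
               "matrix_answer_time_ratio", "visits_per_matrix_cell",
               "visits_per_wrong_answer", "n_fix_matrix",
               "mean_fixdur_matrix_ms", "n_fix_answers",
               "mean_fixdur_answers_ms", "ma_transition_rate_per_s")
  purrr::map_dfr(metrics, function(m) {
    res <- compare_clusters_bf(labeled[[m]], labeled$label)
    dplyr::bind_cols(tibble::tibble(metric = m), res) |>
      dplyr::mutate(direction = dplyr::case_when(
        .data$mean2 > .data$mean1 ~ "cluster 2 higher",
        .data$mean2 < .data$mean1 ~ "cluster 1 higher",
        TRUE ~ "equal"))
  })
}
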