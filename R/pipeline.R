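#' Study analysis configuration
#'
#' Collects the input paths (or in-memory objects), preprocessing
#' thresholds, clustering and modelling options for [run_study()]. Either
#' supply `fixations`/`layout_file`/`scores` paths, or pass a simulated
#' study bundle directly via `study`.
#'
#' @param fixations Path to a fixation CSV/TSV (or `NULL` when `study` is
#'   given).
#' @param layout_file Path to a YAML/JSON layout + item-key config.
#' @param scores Path to a score CSV.
#' @param study Optional in-memory bundle from [simulate_study()].
#' @param model_targets Score columns to model; default: every score column.
#' @param steiger_metrics Gaze metrics whose correlations are compared
#'   across tests; defaults to the dwell ratio, matrix-answer transition
#'   count and wrong-answer visits.
#' @param min_fixation_ms,valid_ratio_min,score_sd_limit Preprocessing
#'   thresholds (see [filter_fixations()], [qc_participants()]).
#' @param restarts Clustering restarts.
#' @param split_fraction,nlambda,lambda_min_ratio Modelling options.
#' @param seed Seed for clustering and splits.
#' @param out_dir Output directory for the written tables (`NULL`: nothing
#'   written).
#' @return A `study_config` list.
#' @export
study_config <- function(fixations = NULL, layout_file = NULL, scores = NULL,
                         study = NULL, model_targets = NULL,
                         steiger_metrics = c("matrix_answer_time_ratio",
                                             "n_ma_transitions",
                                             "visits_per_wrong_answer"),
                         min_fixation_ms = 100, valid_ratio_min = 0.5,
                         score_sd_limit = 3, restarts = 25L,
                         split_fraction = 0.8, nlambda = 100,
                         lambda_min_ratio = 1e-4, seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  if (is.null(study) && (is.null(fixations) || is.null(layout_file))) {
    abort("study_config needs either in-memory `study` or fixation + layout paths",
          class = "gazestrat_config_error")
  }
  structure(cfg, class = "study_config")
}

#' Run the full study analysis
#'
#' Executes the pipeline stages in order: read inputs, tag fixations with
#' AOIs, participant quality control, fixation filtering, the fourteen
#' gaze metrics, two-cluster scanpath classification (with the cluster-2
#' percentage backfilled into the metric table), Bayes-factor cluster
#' contrasts, one LASSO model per requested score target, the correlation
#' matrix with Steiger comparisons and forest-plot intervals, and
#' descriptive summaries. Every stage is a pure function of the inputs and
#' the seed, so rerunning an identical configuration reproduces identical
#' outputs.
#'
#' @param config A [study_config()].
#' @return A report list with elements `qc`, `metrics`, `clusters`,
#'   `cluster_bf`, `models` (per target: fit + performance), `correlations`
#'   (`R`, `steiger`, `forest`), `descriptives`, and `counts`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "gazestrat_pipeline_error")
    })
  }

  inputs <- stage("read", {
    if (!is.null(config$study)) {
      s <- config$study
      list(fix = s$fixations, layout = s$layout, keys = s$keys, scores = s$scores)
    } else {
      lay <- load_aoi_layout(config$layout_file)
      list(fix = read_fixation_table(config$fixations),
           layout = lay$layout, keys = lay$keys,
           scores = if (!is.null(config$scores)) read_score_table(config$scores)
                    else NULL)
    }
  })
  targets <- config$model_targets
  if (is.null(targets) && !is.null(inputs$scores)) {
    targets <- setdiff(names(inputs$scores), "participant_id")
  }
  bad_targets <- setdiff(targets, names(inputs$scores))
  if (length(bad_targets) > 0) {
    abort(sprintf("unknown model target(s): %s", paste(bad_targets, collapse = ", ")),
          class = "gazestrat_config_error")
  }

  tagged <- stage("tag", tag_fixations(inputs$fix, inputs$layout))
  scored_ids <- inputs$keys$trial_id[!inputs$keys$is_practice]
  tagged_scored <- tagged[tagged$trial_id %in% scored_ids, ]
  filtered <- stage("filter",
    filter_fixations(tagged, inputs$keys,
                     min_duration_ms = config$min_fixation_ms))
  qc <- stage("qc",
    qc_participants(tagged_scored, filtered, scores = inputs$scores,
                    keys = inputs$keys,
                    valid_ratio_min = config$valid_ratio_min,
                    score_sd_limit = config$score_sd_limit))
  filtered <- filtered[filtered$participant_id %in% qc$retained, ]

  feats <- stage("features", transition_feature_table(filtered))
  clusters <- stage("cluster",
    fit_two_cluster_model(feats$X, seed = config$seed,
                          restarts = config$restarts))
  labels <- dplyr::mutate(feats$trials, label = clusters$labels)
  metrics <- stage("metrics",
    compute_gaze_metrics(filtered, inputs$keys, cluster_labels = labels))
  per_trial <- stage("trial_metrics", trial_gaze_metrics(filtered, inputs$keys))
  cluster_bf <- stage("cluster_bf",
    cluster_bf_table(per_trial, clusters, feats$trials))

  models <- list()
  correlations <- NULL
  descr_tbl <- metrics[, c("participant_id", gaze_metric_names())]
  if (!is.null(inputs$scores)) {
    joined <- dplyr::inner_join(metrics, inputs$scores, by = "participant_id")
    models <- stage("models", {
      out <- list()
      for (tgt in targets) {
        out[[tgt]] <- run_lasso_model(
          joined, tgt, split_fraction = config$split_fraction,
          seed = config$seed, nlambda = config$nlambda,
          lambda_min_ratio = config$lambda_min_ratio)
      }
      out
    })
    correlations <- stage("correlations", {
      R <- pearson_matrix(joined[, c(gaze_metric_names(), targets)])
      st <- if (length(targets) >= 2) {
        steiger_table(R, config$steiger_metrics, targets)
      } else NULL
      fo <- forest_data(R, config$steiger_metrics, targets)
      list(R = R, steiger = st, forest = fo)
    })
    descr_tbl <- joined[, c("participant_id", gaze_metric_names(), targets)]
  }
  descriptives <- stage("descriptives", describe(descr_tbl))

  report <- list(
    qc = qc, metrics = metrics, clusters = clusters, labels = labels,
    cluster_bf = cluster_bf, models = models, correlations = correlations,
    descriptives = descriptives,
    counts = list(read = length(unique(inputs$fix$participant_id)),
                  retained = length(qc$retained),
                  excluded = sum(qc$report$excluded)))
  stopifnot(report$counts$read == report$counts$retained + report$counts$excluded)

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_table(report$qc$report, file.path(dir, "qc_report.csv"))
  write_table(report$metrics, file.path(dir, "gaze_metrics.csv"))
  write_table(report$labels, file.path(dir, "cluster_labels.csv"))
  write_table(report$cluster_bf, file.path(dir, "cluster_bf.csv"))
  for (k in 1:2) {
    utils::write.csv(centroid_matrix(report$clusters, k),
                     file.path(dir, sprintf("centroid_cluster%d.csv", k)))
  }
  write_table(report$descriptives, file.path(dir, "descriptives.csv"))
  if (!is.null(report$correlations)) {
    utils::write.csv(report$correlations$R, file.path(dir, "correlation_matrix.csv"))
    if (!is.null(report$correlations$steiger)) {
      write_table(report$correlations$steiger, file.path(dir, "steiger_tests.csv"))
    }
    write_table(report$correlations$forest, file.path(dir, "forest_data.csv"))
  }
  for (tgt in names(report$models)) {
    m <- report$models[[tgt]]
    jsonlite::write_json(
      list(target = tgt, lambda = m$fit$lambda, cv_rmse = m$fit$cv_rmse,
           lambda_sel = m$fit$lambda_sel, coefficients = as.list(m$fit$beta),
           intercept = m$fit$intercept, performance = as.list(m$performance),
           train_ids = m$split$train_ids, test_ids = m$split$test_ids),
      file.path(dir, sprintf("model_%s.json", tgt)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Descriptive summary of every numeric column
#'
#' Mean, SD, range, and bias-corrected sample skewness and excess kurtosis
#' (the conventions under which a normal distribution has skewness 0 and
#' kurtosis 0). Columns with fewer than 3 non-missing values or zero
#' variance get `NA` shape statistics and a reason.
#'
#' @param data Data frame; non-numeric columns are ignored.
#' @return Tibble: one row per variable with `n`, `mean`, `sd`, `min`,
#'   `max`, `skewness`, `kurtosis`, `note`.
#' @export
describe <- function(data) {
  num <- data[, vapply(data, is.numeric, logical(1)), drop = FALSE]
  purrr::map_dfr(names(num), function(v) {
    x <- num[[v]][!is.na(num[[v]])]
    n <- length(x)
    base <- tibble::tibble(variable = v, n = n,
                           mean = if (n > 0) mean(x) else NA_real_,
                           sd = if (n > 1) sd(x) else NA_real_,
                           min = if (n > 0) min(x) else NA_real_,
                           max = if (n > 0) max(x) else NA_real_)
    if (n < 3 || sd(x) == 0) {
      return(dplyr::mutate(base, skewness = NA_real_, kurtosis = NA_real_,
                           note = if (n < 3) "fewer than 3 values" else
                             "constant column"))
    }
    # the bias-corrected kurtosis divides by (n-2)(n-3): defined for n >= 4
    dplyr::mutate(base,
                  skewness = e1071::skewness(x, type = 2),
                  kurtosis = if (n >= 4) e1071::kurtosis(x, type = 2) else
                    NA_real_,
                  note = if (n >= 4) "" else "kurtosis needs 4 values")
  })
}
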