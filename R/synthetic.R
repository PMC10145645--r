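m_idx <- function(r, c) 3L * r + c + 1L   # row-major index into aoi10_labels()
ANS_IDX <- 10L

# distribute `mass` over the named target indices, and the remainder
# uniformly over the remaining matrix cells (never self, never ANS)
kernel_row <- function(self, targets) {
  row <- numeric(10)
  row[as.integer(names(targets))] <- targets
  rest <- setdiff(1:9, c(self, as.integer(names(targets))))
  row[rest] <- row[rest] + (1 - sum(targets)) / length(rest)
  stopifnot(abs(sum(row) - 1) < 1e-12, row[self] == 0)
  row
}

#' Strategy kernels for synthetic scanpaths
#'
#' Hand-authored 10-AOI Markov kernels emulating the two scanning
#' strategies the clustering is meant to recover. The *constructive*
#' kernel progresses strictly left-to-right through each matrix row and
#' enters the answer region almost only after the bottom row (classic
#' constructive matching). The *hybrid* kernel mixes row-wise and
#' column-wise moves and enters the answers from the end of any row, with
#' substantially larger total answer-entry mass. `separability` in
#' `[0, 1]` linearly interpolates the hybrid kernel toward the
#' constructive one: at 0 the two strategies are identical (clustering
#' agreement must fall to chance), at 1 they are maximally distinct.
#'
#' @param name `"constructive"` or `"hybrid"`.
#' @param separability Interpolation knob in `[0, 1]`.
#' @return List: `name`, `P` (10x10 row-stochastic, zero diagonal),
#'   `init` (initial AOI distribution), `ans_entry_mass` (total kernel
#'   mass into the answer region).
#' @export
strategy_kernel <- function(name = c("constructive", "hybrid"), separability = 1) {
  name <- match.arg(name)
  stopifnot(separability >= 0, separability <= 1)
  labs <- aoi10_labels()

  constructive <- matrix(0, 10, 10, dimnames = list(labs, labs))
  hybrid <- matrix(0, 10, 10, dimnames = list(labs, labs))
  tg <- function(...) {         # named targets: index = value
    v <- c(...)
    setNames(as.numeric(v), names(v))
  }
  for (r in 0:2) for (c in 0:2) {
    i <- m_idx(r, c)
    nxt_row <- (r + 1L) %% 3L
    if (c < 2) {
      constructive[i, ] <- kernel_row(i, tg(setNames(
        c(0.80, 0.06, 0.02),
        c(m_idx(r, c + 1L), m_idx(nxt_row, 0L), ANS_IDX))))
      hybrid[i, ] <- kernel_row(i, tg(setNames(
        c(0.38, 0.30, 0.12),
        c(m_idx(r, c + 1L), m_idx(nxt_row, c), ANS_IDX))))
    } else if (r < 2) {
      constructive[i, ] <- kernel_row(i, tg(setNames(
        c(0.68, 0.10, 0.04),
        c(m_idx(r + 1L, 0L), m_idx(r, 0L), ANS_IDX))))
      hybrid[i, ] <- kernel_row(i, tg(setNames(
        c(0.22, 0.18, 0.40),
        c(m_idx(r + 1L, 0L), m_idx(nxt_row, 2L), ANS_IDX))))
    } else {                     # bottom-right cell
      constructive[i, ] <- kernel_row(i, tg(setNames(
        c(0.20, 0.55), c(m_idx(0L, 0L), ANS_IDX))))
      hybrid[i, ] <- kernel_row(i, tg(setNames(
        c(0.12, 0.20, 0.45), c(m_idx(0L, 0L), m_idx(0L, 2L), ANS_IDX))))
    }
  }
  constructive[ANS_IDX, ] <- kernel_row(ANS_IDX, tg(setNames(
    c(0.30, 0.20), c(m_idx(0L, 0L), m_idx(2L, 2L)))))
  hybrid[ANS_IDX, ] <- kernel_row(ANS_IDX, tg(setNames(
    c(0.20, 0.10, 0.10), c(m_idx(0L, 0L), m_idx(0L, 2L), m_idx(2L, 2L)))))

  init <- setNames(numeric(10), labs)
  init[m_idx(0L, 0L)] <- 0.6
  init[m_idx(0L, 1L)] <- 0.1
  init[m_idx(1L, 0L)] <- 0.1
  rest <- setdiff(1:9, c(m_idx(0L, 0L), m_idx(0L, 1L), m_idx(1L, 0L)))
  init[rest] <- 0.2 / length(rest)

  P <- if (name == "constructive") constructive else
    (1 - separability) * constructive + separability * hybrid
  list(name = name, P = P, init = init,
       ans_entry_mass = sum(P[1:9, ANS_IDX]))
}

#' Synthetic study configuration
#'
#' Defaults describe a single-session matrix reasoning study: 60
#' participants, 18 scored + 3 practice trials, two latent strategies with
#' per-participant hybrid propensity drawn from Beta(12, 12), negative
#' binomial scanpath lengths (~30 AOI entries per trial), lognormal
#' fixation durations truncated at the 100 ms recorder minimum, and 5%
#' injected noise fixations (sub-threshold or outside every AOI) to
#' exercise the preprocessing filters. Scores are noisy linear functions
#' of standardized true gaze metrics; per score, either `noise_sd` is
#' given or the noise is calibrated so the noiseless linear predictor
#' explains `target_r2` of the score variance.
#'
#' Per-participant lognormal heterogeneity in duration level, answer-run
#' length and scanpath length gives the dwell-ratio, visit and transition
#' metrics partially independent between-participant variance, as in real
#' cohorts where these traits are correlated but not collinear.
#'
#' @param n_participants,n_trials,n_practice Cohort and session sizes.
#' @param separability Kernel separability knob (see [strategy_kernel()]).
#' @param propensity_shape Beta shape parameters for the per-participant
#'   probability of using the hybrid kernel on a trial.
#' @param chain_mu,chain_size Negative binomial parameters for AOI-entry
#'   counts per trial; `chain_mu_sdlog` is the per-participant lognormal
#'   spread of the mean.
#' @param dur_meanlog_matrix,dur_meanlog_answer,dur_sdlog Lognormal
#'   fixation-duration parameters (ms) per AOI side;
#'   `dur_participant_sdlog_*` are per-participant level spreads.
#' @param ans_run_lambda_constructive,ans_run_lambda_hybrid Poisson rates
#'   for extra answer choices browsed per answer-region entry (per
#'   strategy); `ans_run_participant_sdlog` is the participant spread.
#' @param ans_repeat_lambda Poisson rate for repeated fixations within one
#'   answer choice; `ans_repeat_participant_sdlog` its participant spread.
#' @param correct_bias_weight Mean sampling weight of the correct answer
#'   choice relative to each incorrect one when browsing the answer bank
#'   (efficient solvers spend most answer-side gaze on the correct choice);
#'   `correct_bias_sdlog` its per-participant lognormal spread. This trait
#'   gives wrong-answer visits between-participant variance that
#'   answer-answer transition counts do not share.
#' @param matrix_run_lambda Poisson rate for repeated fixations within a
#'   matrix cell; `matrix_run_participant_sdlog` its participant spread.
#' @param deliberation_sdlog Per-participant lognormal spread of a
#'   "deliberation" factor: how much matrix scanning a participant does per
#'   answer-bank check. The factor divides the kernel's answer-entry mass
#'   and lengthens the chain correspondingly, so matrix-side visit and
#'   transition counts vary across participants without moving their
#'   answer-entry counts.
#' @param gap_ms Inter-fixation (saccade) gap.
#' @param noise_frac Fraction of fixations converted to filter-exercising
#'   noise (half sub-100 ms, half outside every AOI).
#' @param scores Named list of score models, each
#'   `list(beta = <named vector over metrics>, target_r2 = <..>)` or
#'   `list(beta = ..., noise_sd = <..>)`.
#' @param seed Master seed; a fixed seed makes the whole study
#'   byte-identical across runs.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_participants = 60L, n_trials = 18L, n_practice = 3L,
                         separability = 1,
                         propensity_shape = c(12, 12),
                         chain_mu = 34, chain_size = 14, chain_mu_sdlog = 0.1,
                         dur_meanlog_matrix = log(260),
                         dur_meanlog_answer = log(230),
                         dur_sdlog = 0.30,
                         dur_participant_sdlog_matrix = 0.35,
                         dur_participant_sdlog_answer = 0.40,
                         ans_run_lambda_constructive = 0.5,
                         ans_run_lambda_hybrid = 1.4,
                         ans_run_participant_sdlog = 0.4,
                         ans_repeat_lambda = 0.3,
                         ans_repeat_participant_sdlog = 0.7,
                         correct_bias_weight = 4,
                         correct_bias_sdlog = 1.4,
                         matrix_run_lambda = 0.3,
                         matrix_run_participant_sdlog = 0.7,
                         deliberation_sdlog = 0.4,
                         gap_ms = 30,
                         noise_frac = 0.05,
                         scores = default_score_models(),
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_participants >= 2, n_trials >= 1, n_practice >= 0,
            separability >= 0, separability <= 1,
            all(propensity_shape > 0), chain_mu > 0, chain_size > 0,
            dur_sdlog >= 0, noise_frac >= 0, noise_frac < 1)
  for (s in cfg$scores) {
    stopifnot(is.numeric(s$beta), !is.null(names(s$beta)),
              all(names(s$beta) %in% gaze_metric_names()))
  }
  structure(cfg, class = "synth_config")
}

#' Default synthetic score models
#'
#' The `reasoning` score loads on exactly three metrics (matrix-answer
#' transitions, dwell ratio, wrong-answer visits) with the noise calibrated
#' to a true R^2 of 0.6 — the planted-signal configuration the model
#' selection layer is expected to recover. Two further scores give the
#' correlation-comparison layer realistic material.
#'
#' @return Named list of score model specs.
#' @export
default_score_models <- function() {
  list(
    reasoning = list(
      beta = c(n_ma_transitions = -0.45, matrix_answer_time_ratio = 0.45,
               visits_per_wrong_answer = -0.45),
      target_r2 = 0.6),
    planning = list(
      beta = c(matrix_answer_time_ratio = 0.45, latency_first_answer_ms = 0.3,
               mean_fixdur_matrix_ms = -0.2),
      target_r2 = 0.25),
    wm = list(
      beta = c(n_ma_transitions = -0.45, visits_per_wrong_answer = -0.35,
               pct_cluster2 = -0.15),
      target_r2 = 0.25)
  )
}

# one trial's AOI fixation labels: a 10-AOI Markov chain expanded into
# concrete answer choices (several choices browsed per answer-region
# entry) and repeated within-AOI fixations on both sides
simulate_trial_aoi <- function(P, init, n_states, ans_lambda, ans_repeat_lambda,
                               matrix_run_lambda, correct_choice,
                               correct_weight) {
  states <- .sim_chain_cpp(P, init, n_states)
  labs <- aoi10_labels()
  is_ans <- states == ANS_IDX
  reps <- 1L + rpois(n_states, ifelse(is_ans, 0, matrix_run_lambda))
  w <- rep(1, 8)
  w[correct_choice + 1L] <- correct_weight
  parts <- vector("list", n_states)
  for (si in which(!is_ans)) parts[[si]] <- rep(labs[states[si]], reps[si])
  for (si in which(is_ans)) {
    m <- 1L + rpois(1L, ans_lambda)
    choices <- integer(m)
    choices[1] <- sample.int(8L, 1L, prob = w) - 1L
    if (m > 1) for (j in 2:m) {
      ok <- setdiff(0:7, choices[j - 1L])
      choices[j] <- sample(ok, 1L, prob = w[ok + 1L])
    }
    creps <- 1L + rpois(m, ans_repeat_lambda)
    parts[[si]] <- rep(sprintf("A_%d", choices), creps)
  }
  unlist(parts, use.names = FALSE)
}

# durations, coordinates and onsets for a whole participant-trial block,
# vectorized over the concatenated AOI labels
emit_fixations <- function(aoi, trial_no, meanlog_m, meanlog_a, sdlog,
                           gap_ms, rects) {
  n <- length(aoi)
  meanlog <- ifelse(is_answer_aoi(aoi), meanlog_a, meanlog_m)
  dur <- rlnorm(n, meanlog, sdlog)
  while (sdlog > 0 && any(dur < 100)) {   # recorder floor: resample rare short draws
    idx <- which(dur < 100)
    dur[idx] <- rlnorm(length(idx), meanlog[idx], sdlog)
  }
  ri <- match(aoi, rects$label)
  wx <- (rects$x1[ri] - rects$x0[ri]) * 0.35
  wy <- (rects$y1[ri] - rects$y0[ri]) * 0.35
  x <- (rects$x0[ri] + rects$x1[ri]) / 2 + runif(n, -wx, wx)
  y <- (rects$y0[ri] + rects$y1[ri]) / 2 + runif(n, -wy, wy)
  g <- cumsum(dur + gap_ms)
  prev <- c(0, g[-n])
  first <- !duplicated(trial_no)
  onset <- prev - prev[first][trial_no]
  list(onset_ms = onset, duration_ms = dur, x_px = x, y_px = y)
}

inject_noise <- function(fix, noise_frac, screen) {
  if (noise_frac <= 0 || nrow(fix) == 0) return(fix)
  hit <- runif(nrow(fix)) < noise_frac
  if (!any(hit)) return(fix)
  idx <- which(hit)
  kind <- runif(length(idx)) < 0.5
  short_idx <- idx[kind]
  out_idx <- idx[!kind]
  fix$duration_ms[short_idx] <- runif(length(short_idx), 40, 95)
  # top margin of the screen lies outside every AOI in the bundled layout
  fix$x_px[out_idx] <- runif(length(out_idx), 0, screen[1])
  fix$y_px[out_idx] <- runif(length(out_idx), 0, 50)
  fix
}

#' Simulate a complete synthetic study
#'
#' Generates fixation tables, AOI layout, item keys, cognitive scores and
#' the planted ground truth for a two-strategy matrix reasoning study.
#' Per participant, a hybrid-strategy propensity is drawn; per trial, the
#' constructive or hybrid kernel is chosen with that propensity and a
#' Markov scanpath is emitted as concrete fixations (durations, jittered
#' in-AOI coordinates, cumulative onsets). True gaze metrics are computed
#' by the package's own preprocessing and metric modules on the clean
#' generated data (with cluster labels taken from the planted strategies),
#' and scores are noisy linear functions of the standardized true metrics.
#'
#' @param config A [synth_config()].
#' @return List: `fixations` (canonical fixation tibble), `layout`, `keys`,
#'   `scores` (participant x score tibble), `truth` (list:
#'   `trial_strategies` with planted per-trial labels, `metrics` with true
#'   participant metrics, `linear_predictors`, `propensity`).
#' @export
simulate_study <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(cfg) {
  bundle <- default_aoi_layout()
  layout <- bundle$layout
  keys <- make_item_keys(cfg$n_trials, cfg$n_practice)
  kern_c <- strategy_kernel("constructive", cfg$separability)
  kern_h <- strategy_kernel("hybrid", cfg$separability)
  stopifnot(cfg$separability == 0 ||
              kern_h$ans_entry_mass > kern_c$ans_entry_mass)
  pids <- sprintf("S%03d", seq_len(cfg$n_participants))

  propensity <- rbeta(cfg$n_participants, cfg$propensity_shape[1],
                      cfg$propensity_shape[2])
  all_fix <- vector("list", cfg$n_participants)
  strat_rows <- vector("list", cfg$n_participants)

  rects <- layout_rects(layout)
  lam_hybrid <- cfg$ans_run_lambda_constructive + cfg$separability *
    (cfg$ans_run_lambda_hybrid - cfg$ans_run_lambda_constructive)

  for (i in seq_len(cfg$n_participants)) {
    mu_i <- cfg$chain_mu * exp(rnorm(1, 0, cfg$chain_mu_sdlog))
    mlog_m <- cfg$dur_meanlog_matrix + rnorm(1, 0, cfg$dur_participant_sdlog_matrix)
    mlog_a <- cfg$dur_meanlog_answer + rnorm(1, 0, cfg$dur_participant_sdlog_answer)
    run_mult <- exp(rnorm(1, 0, cfg$ans_run_participant_sdlog))
    rep_lam_a <- cfg$ans_repeat_lambda * exp(rnorm(1, 0, cfg$ans_repeat_participant_sdlog))
    run_lam_m <- cfg$matrix_run_lambda * exp(rnorm(1, 0, cfg$matrix_run_participant_sdlog))
    cw_i <- cfg$correct_bias_weight * exp(rnorm(1, 0, cfg$correct_bias_sdlog))
    delib_i <- exp(rnorm(1, 0, cfg$deliberation_sdlog))
    kern_c_i <- scale_answer_mass(kern_c, 1 / delib_i)
    kern_h_i <- scale_answer_mass(kern_h, 1 / delib_i)
    hybrid_trial <- runif(nrow(keys)) < propensity[i]
    aoi_parts <- vector("list", nrow(keys))
    for (tix in seq_len(nrow(keys))) {
      kern <- if (hybrid_trial[tix]) kern_h_i else kern_c_i
      lam_a <- run_mult * if (hybrid_trial[tix]) lam_hybrid else
        cfg$ans_run_lambda_constructive
      n_states <- max(4L, rnbinom(1L, mu = mu_i * delib_i,
                                  size = cfg$chain_size))
      aoi_parts[[tix]] <- simulate_trial_aoi(kern$P, kern$init, n_states,
                                             lam_a, rep_lam_a, run_lam_m,
                                             keys$correct_choice[tix], cw_i)
    }
    n_per_trial <- lengths(aoi_parts)
    trial_no <- rep(seq_len(nrow(keys)), n_per_trial)
    em <- emit_fixations(unlist(aoi_parts, use.names = FALSE), trial_no,
                         mlog_m, mlog_a, cfg$dur_sdlog, cfg$gap_ms, rects)
    all_fix[[i]] <- tibble::tibble(
      participant_id = pids[i],
      trial_id = keys$trial_id[trial_no],
      trial_index = trial_no,
      onset_ms = em$onset_ms, duration_ms = em$duration_ms,
      x_px = em$x_px, y_px = em$y_px)
    strat_rows[[i]] <- tibble::tibble(
      participant_id = pids[i], trial_id = keys$trial_id,
      trial_index = seq_len(nrow(keys)), is_practice = keys$is_practice,
      strategy = ifelse(hybrid_trial, "hybrid", "constructive"),
      label = ifelse(hybrid_trial, 2L, 1L))
  }

  fixations <- inject_noise(dplyr::bind_rows(all_fix), cfg$noise_frac,
                            layout$screen)
  trial_strategies <- dplyr::bind_rows(strat_rows)

  tagged <- tag_fixations(fixations, layout)
  filtered <- filter_fixations(tagged, keys)
  planted_labels <- trial_strategies[!trial_strategies$is_practice,
                                     c("participant_id", "trial_id", "label")]
  metrics <- compute_gaze_metrics(filtered, keys, cluster_labels = planted_labels)

  scores <- tibble::tibble(participant_id = metrics$participant_id)
  lp_tbl <- tibble::tibble(participant_id = metrics$participant_id)
  for (sn in names(cfg$scores)) {
    sm <- cfg$scores[[sn]]
    Xz <- scale(as.matrix(metrics[, names(sm$beta)]))
    # a zero-variance metric carries no individual differences: its
    # standardized contribution to the score is zero, not NaN
    zero_var <- !is.na(attr(Xz, "scaled:scale")) & attr(Xz, "scaled:scale") == 0
    Xz[, zero_var] <- 0
    lp <- drop(Xz %*% sm$beta)
    noise_sd <- if (!is.null(sm$noise_sd)) sm$noise_sd else {
      stopifnot(!is.null(sm$target_r2), sm$target_r2 > 0, sm$target_r2 <= 1)
      # participants with missing metrics get NA scores; exclude them here
      sd(lp, na.rm = TRUE) * sqrt((1 - sm$target_r2) / sm$target_r2)
    }
    scores[[sn]] <- lp + rnorm(length(lp), 0, noise_sd)
    lp_tbl[[sn]] <- lp
  }

  list(fixations = fixations, layout = layout, keys = keys, scores = scores,
       truth = list(trial_strategies = trial_strategies, metrics = metrics,
                    linear_predictors = lp_tbl,
                    propensity = setNames(propensity, pids)))
}

# multiply every row's answer-entry probability by `f` (capped) and
# redistribute the difference over that row's matrix-cell mass; the
# participant-level deliberation factor passes f = 1/delib
scale_answer_mass <- function(kern, f) {
  P <- kern$P
  for (i in 1:9) {
    a_old <- P[i, ANS_IDX]
    a_new <- min(a_old * f, 0.85)
    P[i, 1:9] <- P[i, 1:9] * (1 - a_new) / (1 - a_old)
    P[i, ANS_IDX] <- a_new
  }
  kern$P <- P
  kern$ans_entry_mass <- sum(P[1:9, ANS_IDX])
  kern
}

make_item_keys <- function(n_trials, n_practice) {
  base <- default_item_keys()
  scored <- base[!base$is_practice, ]
  practice <- base[base$is_practice, ]
  if (n_practice > nrow(practice) || n_trials > nrow(scored)) {
    correct <- rep(c(3, 5, 0, 2, 7, 1, 4, 6), length.out = n_practice + n_trials)
    return(tibble::tibble(
      trial_id = c(sprintf("P%d", seq_len(n_practice)),
                   sprintf("T%02d", seq_len(n_trials))),
      correct_choice = correct,
      is_practice = c(rep(TRUE, n_practice), rep(FALSE, n_trials))))
  }
  dplyr::bind_rows(practice[seq_len(n_practice), ], scored[seq_len(n_trials), ])
}

#' Write a synthetic study to disk in the standard interchange formats
#'
#' Fixations and scores as CSV, layout + keys as YAML, ground truth as JSON.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fixation_table(study$fixations, file.path(dir, "fixations.csv"))
  write_table(study$scores, file.path(dir, "scores.csv"))
  write_aoi_layout(study$layout, study$keys, file.path(dir, "layout.yaml"))
  truth <- list(
    trial_strategies = study$truth$trial_strategies,
    metrics = study$truth$metrics,
    linear_predictors = study$truth$linear_predictors,
    propensity = as.list(study$truth$propensity))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
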