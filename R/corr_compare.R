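#' Pearson correlation matrix with pairwise-complete observations
#'
#' @param data Tibble or data frame; non-numeric columns are dropped.
#' @param min_n Minimum complete rows required for every pair.
#' @return Symmetric correlation matrix with unit diagonal; the pairwise
#'   complete-sample sizes are attached as `attr(, "n")`.
#' @export
pearson_matrix <- function(data, min_n = 4L) {
  num <- data[, vapply(data, is.numeric, logical(1)), drop = FALSE]
  if (ncol(num) < 2) abort("need at least two numeric columns",
                           class = "gazestrat_corr_error")
  zero_var <- names(num)[vapply(num, function(v) {
    s <- sd(v, na.rm = TRUE); !is.finite(s) || s == 0
  }, logical(1))]
  if (length(zero_var) > 0) {
    abort(sprintf("zero-variance column(s): %s", paste(zero_var, collapse = ", ")),
          class = "gazestrat_corr_error")
  }
  M <- as.matrix(num)
  obs <- !is.na(M)
  n_pair <- crossprod(obs)
  if (any(n_pair < min_n)) {
    abort(sprintf("fewer than %d complete observations for some variable pair", min_n),
          class = "gazestrat_corr_error")
  }
  R <- cor(M, use = "pairwise.complete.obs")
  attr(R, "n") <- n_pair
  R
}

#' Steiger's test for two dependent correlations sharing a variable
#'
#' Compares `r_jk` with `r_jh` — the correlations of a shared variable j
#' (here, a gaze metric) with two different variables k and h (two
#' cognitive tests) measured in the same sample — using Fisher's z
#' transform and the asymptotic z-test with the Dunn-Clark covariance term
#' for correlations sharing one variable, evaluated at the individual
#' sample correlations. With `ignore_sign = TRUE` (the default) the two
#' compared correlations enter as absolute values, so the test asks whether
#' the *strengths* of association differ; `r_kh` stays signed.
#'
#' @param r_jk,r_jh The two correlations sharing variable j.
#' @param r_kh Correlation between the two compared variables.
#' @param n Sample size (>= 4).
#' @param ignore_sign Compare correlation magnitudes rather than signed
#'   values.
#' @return One-row tibble: the inputs, `z`, the two-tailed `p`, and
#'   `sign_ignored`.
#' @export
steiger_test <- function(r_jk, r_jh, r_kh, n, ignore_sign = TRUE) {
  if (n < 4) abort("Steiger's test needs n >= 4", class = "gazestrat_corr_error")
  if (any(abs(c(r_jk, r_jh, r_kh)) >= 1)) {
    abort("correlations must lie strictly inside (-1, 1)",
          class = "gazestrat_corr_error")
  }
  r1 <- if (ignore_sign) abs(r_jk) else r_jk
  r2 <- if (ignore_sign) abs(r_jh) else r_jh
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  # Dunn-Clark covariance between the Fisher z's of two correlations that
  # share one variable, at the sample correlations
  psi <- r_kh * (1 - r1^2 - r2^2) - 0.5 * r1 * r2 * (1 - r1^2 - r2^2 - r_kh^2)
  s12 <- psi / ((1 - r1^2) * (1 - r2^2))
  z <- (z1 - z2) * sqrt(n - 3) / sqrt(2 - 2 * s12)
  tibble::tibble(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh, n = n,
                 z = z, p = 2 * pnorm(-abs(z)), sign_ignored = ignore_sign)
}

#' Fisher-z confidence interval for a correlation
#'
#' `tanh(atanh(r) +/- z_crit / sqrt(n - 3))`; the numeric content of a
#' correlation forest plot.
#'
#' @param r Sample correlation, `|r| < 1`.
#' @param n Sample size (>= 4).
#' @param level Confidence level.
#' @return One-row tibble: `r`, `n`, `lo`, `hi`, `level`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n < 4) abort("need n >= 4", class = "gazestrat_corr_error")
  if (abs(r) >= 1) abort("|r| must be < 1", class = "gazestrat_corr_error")
  zc <- qnorm(1 - (1 - level) / 2)
  lo <- tanh(atanh(r) - zc / sqrt(n - 3))
  hi <- tanh(atanh(r) + zc / sqrt(n - 3))
  tibble::tibble(r = r, n = n, lo = lo, hi = hi, level = level)
}

#' Steiger comparisons of a metric's correlations across test pairs
#'
#' For each gaze metric in `metrics` and each unordered pair of score
#' columns in `tests`, runs [steiger_test()] on the entries of a
#' correlation matrix, using the minimum pairwise-complete n of the three
#' involved pairs.
#'
#' @param R Correlation matrix from [pearson_matrix()] (with `n` attribute)
#'   whose rows/columns include `metrics` and `tests`.
#' @param metrics Character vector of shared-variable (gaze metric) names.
#' @param tests Character vector of compared-variable (cognitive test)
#'   names, length >= 2.
#' @param ignore_sign Passed to [steiger_test()].
#' @return Tibble with one row per (metric, test pair).
#' @export
steiger_table <- function(R, metrics, tests, ignore_sign = TRUE) {
  n_pair <- attr(R, "n")
  pairs <- utils::combn(tests, 2, simplify = FALSE)
  purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(pairs, function(pr) {
      k <- pr[1]; h <- pr[2]
      n <- min(n_pair[m, k], n_pair[m, h], n_pair[k, h])
      res <- steiger_test(R[m, k], R[m, h], R[k, h], n, ignore_sign)
      dplyr::bind_cols(tibble::tibble(metric = m, test_k = k, test_h = h), res)
    })
  })
}

#' Forest-plot data: correlations and Fisher-z intervals
#'
#' @param R Correlation matrix from [pearson_matrix()].
#' @param metrics,tests Row/column name selections.
#' @param level Confidence level.
#' @return Tibble: `metric`, `test`, `r`, `n`, `lo`, `hi`.
#' @export
forest_data <- function(R, metrics, tests, level = 0.95) {
  n_pair <- attr(R, "n")
  purrr::map_dfr(metrics, function(m) {
    purrr::map_dfr(tests, function(tst) {
      ci <- fisher_ci(R[m, tst], n_pair[m, tst], level)
      tibble::tibble(metric = m, test = tst, r = ci$r, n = ci$n,
                     lo = ci$lo, hi = ci$hi)
    })
  })
}
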