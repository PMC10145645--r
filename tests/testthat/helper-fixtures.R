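# shared fixture builders and independent oracles

bundled_layout <- function() default_aoi_layout()

# center of a named AOI rectangle in the bundled layout
aoi_center <- function(label, layout = bundled_layout()$layout) {
  r <- gazestrat:::layout_rects(layout)
  i <- match(label, r$label)
  c(x = (r$x0[i] + r$x1[i]) / 2, y = (r$y0[i] + r$y1[i]) / 2)
}

# build a one-participant fixation tibble from (trial_id, onset, dur, label)
# rows; label "OUT" places the point in the top screen margin
make_fixations <- function(rows, participant = "P1",
                           layout = bundled_layout()$layout) {
  keys_all <- bundled_layout()$keys
  tibble::tibble(
    participant_id = participant,
    trial_id = vapply(rows, `[[`, character(1), 1),
    trial_index = match(vapply(rows, `[[`, character(1), 1), keys_all$trial_id),
    onset_ms = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    duration_ms = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1)),
    x_px = vapply(rows, function(r) {
      if (r[[4]] == "OUT") 10 else aoi_center(r[[4]], layout)[["x"]]
    }, numeric(1)),
    y_px = vapply(rows, function(r) {
      if (r[[4]] == "OUT") 10 else aoi_center(r[[4]], layout)[["y"]]
    }, numeric(1))
  )
}

# a small, fast synthetic study for pipeline-level tests (16 participants
# keeps an 80/20 split viable: 13 train / 3 test)
small_config <- function(seed = 7, ...) {
  synth_config(n_participants = 16L, chain_mu = 15, seed = seed, ...)
}

# exhaustive two-cluster SSE oracle over all non-empty bipartitions
exhaustive_two_cluster_sse <- function(X) {
  n <- nrow(X)
  stopifnot(n <= 10)
  best <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    if (!any(grp) || all(grp)) next
    sse <- 0
    for (g in list(grp, !grp)) {
      Xi <- X[g, , drop = FALSE]
      ctr <- colMeans(Xi)
      sse <- sse + sum(sweep(Xi, 2, ctr)^2)
    }
    if (sse < best) best <- sse
  }
  best
}

# independent JZS Bayes-factor oracle: Gauss-Kronrod quadrature on the
# transformed domain u = g / (1 + g)
jzs_bf10_oracle <- function(t, n1, n2, rscale = sqrt(2) / 2) {
  nu <- n1 + n2 - 2
  N <- n1 * n2 / (n1 + n2)
  r2 <- rscale^2
  h1 <- function(g) {
    exp(-0.5 * log1p(N * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) +
          (nu + 1) / 2 * log1p(t^2 / nu) +   # divide out the H0 likelihood
          0.5 * log(r2 / 2) - lgamma(0.5) - 1.5 * log(g) - r2 / (2 * g))
  }
  f <- function(u) h1(u / (1 - u)) / (1 - u)^2
  pracma::quadgk(f, 1e-12, 1 - 1e-12, tol = 1e-10)
}

# closed-form least squares via the normal equations (with intercept)
ols_oracle <- function(X, y) {
  Xi <- cbind(1, as.matrix(X))
  drop(solve(crossprod(Xi), crossprod(Xi, y)))
}

# random collapsed AOI sequence over the 17 concrete labels
random_collapsed_seq <- function(len, labels = aoi17_labels()) {
  s <- sample(labels, len, replace = TRUE)
  collapse_aoi_sequence(s)
}
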