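#' Split participants and standardize with train statistics
#'
#' Seeded random participant-level split into a training and a test part
#' (train size = `round(split_fraction * n)`), then z-scoring of every
#' predictor and the response using the training means and SDs only, so no
#' information leaks from the test part into the standardization. Rows with
#' any missing value among the used columns are dropped first (their count
#' is reported).
#'
#' @param data Tibble with `participant_id`, the predictor columns and the
#'   response column.
#' @param response Name of the response column.
#' @param predictors Character vector of predictor column names; defaults
#'   to the fourteen gaze metrics.
#' @param split_fraction Training fraction in (0, 1).
#' @param seed Integer seed for the partition.
#' @return List: `train`, `test` (standardized tibbles), `center`/`scale`
#'   (named vectors over predictors and response), `dropped` (ids of rows
#'   removed for missingness), `train_ids`, `test_ids`.
#' @export
split_and_standardize <- function(data, response,
                                  predictors = gaze_metric_names(),
                                  split_fraction = 0.8, seed = 1L) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  cols <- c(predictors, response)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("data lacks column(s): %s", paste(missing_cols, collapse = ", ")),
          class = "gazestrat_model_error")
  }
  complete <- stats::complete.cases(data[, cols])
  dropped <- data$participant_id[!complete]
  data <- data[complete, , drop = FALSE]
  n <- nrow(data)
  n_train <- round(split_fraction * n)
  if (n_train < 3 || n - n_train < 3) {
    abort("split leaves fewer than 3 rows in one part", class = "gazestrat_model_error")
  }
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  train <- data[idx, , drop = FALSE]
  test <- data[-idx, , drop = FALSE]
  center <- vapply(train[, cols], mean, numeric(1))
  scale_ <- vapply(train[, cols], sd, numeric(1))
  zero <- names(scale_)[scale_ == 0 | !is.finite(scale_)]
  if (length(zero) > 0) {
    abort(sprintf("zero-variance column(s) on the training part: %s",
                  paste(zero, collapse = ", ")),
          class = "gazestrat_model_error")
  }
  zscore <- function(d) {
    for (cc in cols) d[[cc]] <- (d[[cc]] - center[[cc]]) / scale_[[cc]]
    d
  }
  list(train = zscore(train), test = zscore(test),
       center = center, scale = scale_, dropped = dropped,
       train_ids = train$participant_id, test_ids = test$participant_id)
}

#' Smallest penalty that zeroes every LASSO coefficient
#'
#' For the objective `(1/(2n)) ||y - b0 - X beta||^2 + lambda ||beta||_1`
#' (columns centered internally), the all-zero solution is optimal exactly
#' when `lambda >= max_j |x_j' y| / n` on the centered data.
#'
#' @param X Predictor matrix.
#' @param y Response vector.
#' @return The analytic threshold `lambda_max`.
#' @export
lasso_lambda_max <- function(X, y) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  y <- y - mean(y)
  max(abs(crossprod(X, y))) / length(y)
}

#' Coordinate-descent LASSO solver
#'
#' Minimizes `(1/(2n)) ||y - b0 - X beta||^2 + lambda ||beta||_1` by cyclic
#' coordinate descent with soft-thresholding. Predictors and response are
#' centered internally (the intercept is recovered afterwards) but not
#' rescaled, so the caller controls standardization. Convergence is
#' declared when the largest coefficient change in a sweep falls below
#' `tol`; exceeding `max_sweeps` is an error carrying the offending lambda.
#'
#' @param X Numeric predictor matrix (n x p).
#' @param y Numeric response (length n).
#' @param lambda Non-negative penalty.
#' @param beta0 Optional warm-start coefficients.
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_sweeps Sweep budget; the solver stops here even when `tol`
#'   has not been reached (`converged` reports which rule fired). Among
#'   strongly collinear predictors the last digits of the split between
#'   near-duplicate coefficients can converge arbitrarily slowly while
#'   predictions are long since stable, so the cap is a stopping rule, not
#'   an error.
#' @return List: `beta` (named), `intercept`, `lambda`, `sweeps`,
#'   `converged`.
#' @export
lasso_cd <- function(X, y, lambda, beta0 = NULL, tol = 1e-8, max_sweeps = 1e5,
                     gram = NULL) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(gram)) gram <- lasso_gram(X, y)
  G <- gram$G; q <- gram$q
  beta <- if (is.null(beta0)) numeric(p) else as.numeric(beta0)
  sweeps <- 0L
  converged <- FALSE
  sweep_once <- function(idx) {
    delta <- 0
    for (j in idx) {
      if (G[j, j] == 0) next
      bj_old <- beta[j]
      rho <- q[j] - sum(G[j, ] * beta) + G[j, j] * bj_old
      bj <- soft_threshold(rho, lambda) / G[j, j]
      if (bj != bj_old) {
        beta[j] <<- bj
        delta <- max(delta, abs(bj - bj_old))
      }
    }
    delta
  }
  # glmnet-style active-set cycling: full sweeps establish the active set,
  # inner sweeps iterate it to tolerance, a final full sweep checks KKT
  repeat {
    sweeps <- sweeps + 1L
    delta <- sweep_once(seq_len(p))
    if (delta < tol) { converged <- TRUE; break }
    if (sweeps >= max_sweeps) break
    active <- which(beta != 0)
    repeat {
      sweeps <- sweeps + 1L
      d2 <- sweep_once(active)
      if (d2 < tol || sweeps >= max_sweeps) break
    }
    if (sweeps >= max_sweeps) break
  }
  names(beta) <- colnames(X)
  list(beta = beta, intercept = gram$ym - sum(gram$xm * beta), lambda = lambda,
       sweeps = sweeps, converged = converged)
}

# centered second moments reused across a lambda path / LOOCV folds
lasso_gram <- function(X, y) {
  n <- nrow(X)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  list(G = crossprod(Xc) / n, q = drop(crossprod(Xc, y - ym)) / n,
       xm = xm, ym = ym)
}

soft_threshold <- function(z, gamma) sign(z) * max(abs(z) - gamma, 0)

#' Penalty grid from the analytic threshold
#'
#' @param X,y Training data (standardized or not).
#' @param nlambda Grid length.
#' @param lambda_min_ratio Smallest grid value relative to `lambda_max`.
#' @return Decreasing numeric vector.
#' @export
lasso_lambda_grid <- function(X, y, nlambda = 100, lambda_min_ratio = 1e-4) {
  lmax <- lasso_lambda_max(X, y)
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

# fit the whole lambda path with warm starts; returns p x L coefficient
# matrix and intercept vector
lasso_path <- function(X, y, lambdas, tol = 1e-8, max_sweeps = 1e5,
                       beta0 = NULL) {
  gram <- lasso_gram(as.matrix(X), y)
  if (is.null(beta0)) beta0 <- numeric(ncol(X))
  res <- .cd_path_cpp(gram$G, gram$q, lambdas, tol, as.integer(max_sweeps),
                      beta0)
  B <- res$beta
  rownames(B) <- colnames(X)
  a0 <- gram$ym - drop(crossprod(B, gram$xm))
  list(beta = B, intercept = a0, nonconv = sum(!res$converged))
}

#' LASSO with the penalty chosen by leave-one-out cross-validation
#'
#' For every value of a log-spaced penalty grid running from the analytic
#' all-zero threshold `lambda_max` down to `lambda_min_ratio * lambda_max`,
#' the leave-one-out RMSE is computed by refitting the model on each
#' n-1-row training subset (warm-started along the path) and predicting the
#' held-out row. The selected penalty minimizes the LOOCV RMSE, ties broken
#' toward the larger (more parsimonious) penalty; the final coefficients
#' are refit on the full training part at that penalty.
#'
#' Fold fits use a smaller sweep budget (`cv_max_sweeps`) than the final
#' refit: among near-collinear predictors the slowly-converging coefficient
#' component is prediction-invariant (the fitted values stabilize orders of
#' magnitude earlier than the coefficient split between near-duplicates),
#' so held-out predictions — all the folds are used for — are unaffected.
#'
#' @param train Standardized training tibble (see [split_and_standardize()]).
#' @param response Response column name.
#' @param predictors Predictor column names.
#' @param nlambda,lambda_min_ratio Grid parameters.
#' @param tol Coordinate-descent tolerance.
#' @param cv_max_sweeps Sweep budget per fold fit.
#' @param max_sweeps Sweep budget for the final refit.
#' @return Object of class `lasso_fit`: `lambda` (grid), `cv_rmse` (curve),
#'   `lambda_sel`, `beta` (named coefficients at `lambda_sel`), `intercept`,
#'   `n_train`, plus the response/predictor names.
#' @export
fit_lasso_loocv <- function(train, response, predictors = gaze_metric_names(),
                            nlambda = 100, lambda_min_ratio = 1e-4, tol = 1e-8,
                            cv_max_sweeps = 1e3, max_sweeps = 1e5) {
  X <- as.matrix(train[, predictors])
  y <- train[[response]]
  n <- nrow(X)
  if (n < 3) abort("need at least 3 training rows", class = "gazestrat_model_error")
  lambdas <- lasso_lambda_grid(X, y, nlambda, lambda_min_ratio)
  errs <- matrix(NA_real_, n, length(lambdas))
  for (i in seq_len(n)) {
    path <- lasso_path(X[-i, , drop = FALSE], y[-i], lambdas, tol = tol,
                       max_sweeps = cv_max_sweeps)
    errs[i, ] <- y[i] - (X[i, , drop = FALSE] %*% path$beta + path$intercept)
  }
  cv_rmse <- sqrt(colMeans(errs^2))
  sel <- which.min(cv_rmse)   # grid is decreasing, so the first minimum is the largest lambda
  # warm-start down the path at the fold budget, then polish the selected
  # lambda at the full budget
  warm <- lasso_path(X, y, lambdas[seq_len(sel)], tol = tol,
                     max_sweeps = cv_max_sweeps)
  final <- lasso_path(X, y, lambdas[sel], tol = tol, max_sweeps = max_sweeps,
                      beta0 = warm$beta[, sel])
  if (final$nonconv > 0) {
    warn("final refit hit the sweep cap at the selected lambda")
  }
  structure(list(lambda = lambdas, cv_rmse = cv_rmse,
                 lambda_sel = lambdas[sel],
                 beta = final$beta[, 1],
                 intercept = final$intercept[1],
                 n_train = n, response = response, predictors = predictors),
            class = "lasso_fit")
}

#' @export
print.lasso_fit <- function(x, ...) {
  nz <- sum(x$beta != 0)
  cat(sprintf("<lasso_fit> response '%s', lambda* = %.5g, %d/%d nonzero coefficients\n",
              x$response, x$lambda_sel, nz, length(x$beta)))
  invisible(x)
}

#' @export
predict.lasso_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$predictors])
  drop(X %*% object$beta + object$intercept)
}

#' Test-set performance of a LASSO fit
#'
#' Pearson correlation of predictions with observations, `R^2 = 1 -
#' SS_res/SS_tot` (SS_tot about the test-set response mean, so R^2 can be
#' negative when the model predicts worse than the test mean), mean
#' absolute error and root-mean-squared error. With a standardized
#' response, MAE and RMSE are in standard-deviation units.
#'
#' @param fit A `lasso_fit`.
#' @param test Standardized test tibble (same standardization as training).
#' @return One-row tibble: `r`, `r2`, `mae`, `rmse`, `n_test`.
#' @export
evaluate_on_test <- function(fit, test) {
  if (nrow(test) < 3) abort("test set needs at least 3 rows",
                            class = "gazestrat_model_error")
  y <- test[[fit$response]]
  yhat <- predict(fit, test)
  resid <- y - yhat
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r <- if (sd(yhat) == 0) NA_real_ else cor(y, yhat)
  tibble::tibble(r = r, r2 = 1 - ss_res / ss_tot,
                 mae = mean(abs(resid)), rmse = sqrt(mean(resid^2)),
                 n_test = length(y))
}

#' Fit and evaluate one prediction model end to end
#'
#' Convenience wrapper: split, standardize, select the penalty by LOOCV,
#' refit, and evaluate on the held-out part.
#'
#' @inheritParams split_and_standardize
#' @inheritParams fit_lasso_loocv
#' @return List: `split`, `fit`, `performance`.
#' @export
run_lasso_model <- function(data, response, predictors = gaze_metric_names(),
                            split_fraction = 0.8, seed = 1L, nlambda = 100,
                            lambda_min_ratio = 1e-4) {
  sp <- split_and_standardize(data, response, predictors, split_fraction, seed)
  fit <- fit_lasso_loocv(sp$train, response, predictors, nlambda, lambda_min_ratio)
  perf <- evaluate_on_test(fit, sp$test)
  list(split = sp, fit = fit, performance = perf)
}
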