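make_regression_data <- function(n, beta, noise_sd = 0.3, seed = 1) {
  p <- length(gaze_metric_names())
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, gaze_metric_names()))
    y <- drop(X %*% beta) + rnorm(n, 0, noise_sd)
  })
  d <- tibble::as_tibble(as.data.frame(X))
  d$participant_id <- sprintf("S%03d", seq_len(n))
  d$score <- y
  d
}

test_that("the participant split standardizes with train statistics only", {
  beta <- setNames(numeric(14), gaze_metric_names())
  d <- make_regression_data(60, beta)
  sp <- split_and_standardize(d, "score")
  expect_equal(nrow(sp$train), 48)                 # round(0.8 * 60)
  expect_equal(nrow(sp$test), 12)
  for (cc in c(gaze_metric_names(), "score")) {
    expect_equal(mean(sp$train[[cc]]), 0, tolerance = 1e-9)
    expect_equal(sd(sp$train[[cc]]), 1, tolerance = 1e-9)
  }
  # test columns are scaled with train stats, so generally not exactly 0/1
  sp2 <- split_and_standardize(d, "score")
  expect_identical(sp2$train_ids, sp$train_ids)    # same seed, same split
  sp3 <- split_and_standardize(d, "score", seed = 99)
  expect_false(identical(sp3$train_ids, sp$train_ids))

  d$avg_item_time_s <- 5
  expect_error(split_and_standardize(d, "score"), "avg_item_time_s",
               class = "gazestrat_model_error")
})

test_that("the all-zero solution appears exactly at the analytic threshold", {
  beta <- setNames(c(0.8, -0.5, rep(0, 12)), gaze_metric_names())
  d <- make_regression_data(50, beta)
  X <- as.matrix(d[, gaze_metric_names()]); y <- d$score
  lmax <- lasso_lambda_max(X, y)
  expect_true(all(lasso_cd(X, y, lmax)$beta == 0))
  expect_true(all(lasso_cd(X, y, lmax * 1.01)$beta == 0))
  expect_true(any(lasso_cd(X, y, lmax * 0.99)$beta != 0))
})

test_that("at vanishing penalty the solver matches closed-form least squares", {
  beta3 <- c(x1 = 0.7, x2 = -0.4, x3 = 0.2)
  withr::local_seed(11)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, names(beta3)))
  y <- drop(X %*% beta3) + rnorm(80, 0, 0.2)
  fit <- lasso_cd(X, y, lambda = 1e-10)
  ref <- ols_oracle(X, y)
  expect_equal(fit$intercept, ref[1], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(unname(fit$beta), unname(ref[-1]), tolerance = 1e-6)
})

test_that("the compiled path solver agrees with the reference solver and glmnet", {
  beta <- setNames(c(0.8, -0.5, 0.3, rep(0, 11)), gaze_metric_names())
  d <- make_regression_data(40, beta, seed = 3)
  X <- as.matrix(d[, gaze_metric_names()]); y <- d$score
  lambdas <- lasso_lambda_grid(X, y, nlambda = 12, lambda_min_ratio = 1e-2)
  path <- gazestrat:::lasso_path(X, y, lambdas)
  for (l in seq_along(lambdas)) {
    single <- lasso_cd(X, y, lambdas[l])
    expect_equal(unname(path$beta[, l]), unname(single$beta), tolerance = 1e-7)
  }
  skip_if_not_installed("glmnet")
  g <- glmnet::glmnet(X, y, lambda = lambdas, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(as.matrix(g$beta), path$beta, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("the LOOCV curve equals a brute-force loop of independent refits", {
  beta <- setNames(c(0.9, rep(0, 13)), gaze_metric_names())
  d <- make_regression_data(14, beta, seed = 5)
  sp_train <- d                                     # use all rows as training
  fit <- fit_lasso_loocv(sp_train, "score", nlambda = 20,
                         lambda_min_ratio = 1e-2)
  X <- as.matrix(d[, gaze_metric_names()]); y <- d$score
  errs <- matrix(NA_real_, nrow(X), 20)
  for (i in seq_len(nrow(X))) {
    for (l in seq_along(fit$lambda)) {
      f <- lasso_cd(X[-i, ], y[-i], fit$lambda[l])
      errs[i, l] <- y[i] - (sum(X[i, ] * f$beta) + f$intercept)
    }
  }
  expect_equal(fit$cv_rmse, sqrt(colMeans(errs^2)), tolerance = 1e-6)
  expect_equal(fit$lambda_sel, fit$lambda[which.min(fit$cv_rmse)])
})

test_that("a planted single predictor dominates the selected model", {
  beta <- setNames(numeric(14), gaze_metric_names())
  beta[3] <- 0.8
  d <- make_regression_data(200, beta, noise_sd = 0.3, seed = 7)
  res <- run_lasso_model(d, "score", seed = 7)
  b <- res$fit$beta
  expect_gt(b[[3]], 0)
  expect_equal(names(which.max(abs(b))), gaze_metric_names()[3])
})

test_that("test-set performance estimates behave definitionally", {
  obs <- c(-1.2, 0.3, 0.8, 1.4, -0.5)
  fake_fit <- structure(list(beta = c(z = 1), intercept = 0, response = "y",
                             predictors = "z"), class = "lasso_fit")
  perfect <- tibble::tibble(z = obs, y = obs)
  p1 <- evaluate_on_test(fake_fit, perfect)
  expect_equal(p1$r, 1); expect_equal(p1$r2, 1)
  expect_equal(p1$mae, 0); expect_equal(p1$rmse, 0)

  # constant prediction at the test mean -> R^2 = 0
  const_fit <- structure(list(beta = c(z = 0), intercept = mean(obs),
                              response = "y", predictors = "z"),
                         class = "lasso_fit")
  p2 <- evaluate_on_test(const_fit, tibble::tibble(z = obs, y = obs))
  expect_equal(p2$r2, 0)
  expect_true(is.na(p2$r))

  # anti-correlated construction -> negative R^2
  mono <- c(-2, -1, 0, 1, 2)
  p3 <- evaluate_on_test(fake_fit, tibble::tibble(z = rev(mono), y = mono))
  expect_equal(p3$r, -1)
  expect_lt(p3$r2, 0)

  expect_error(evaluate_on_test(fake_fit, perfect[1:2, ]),
               class = "gazestrat_model_error")
})
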