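test_that("OLS recovers exact linear relationships", {
  expect_equal(fit_ols(matrix(c(1, 2, 3)), c(2, 4, 6)), 2)
  set.seed(1)
  X <- matrix(rnorm(40 * 15), 40, 15)
  b_star <- rnorm(15)
  expect_equal(fit_ols(X, drop(X %*% b_star)), b_star, tolerance = 1e-8)
  expect_error(fit_ols(matrix(numeric(0), 0, 3), numeric(0)),
               class = "respgate_input_error")
})

test_that("OLS agrees with the explicit normal-equations oracle", {
  set.seed(2)
  X <- matrix(rnorm(50 * 15), 50, 15)
  y <- rnorm(50)
  expect_lt(max(abs(fit_ols(X, y) - ols_normal_equations(X, y))), 1e-8)
})

test_that("rank-deficient OLS returns the deterministic minimum-norm solution", {
  set.seed(3)
  X <- matrix(rnorm(30 * 5), 30, 5)
  X <- cbind(X, X[, 1] + X[, 2])           # exactly collinear column
  y <- rnorm(30)
  b <- fit_ols(X, y)
  # any solution predicts identically; minimum-norm is reproducible
  expect_equal(b, fit_ols(X, y))
  # residual is orthogonal to the column space
  expect_lt(max(abs(crossprod(X, y - drop(X %*% b)))), 1e-8)
})

test_that("ridge reduces to OLS at zero penalty and shrinks on orthonormal inputs", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  f0 <- fit_ridge(X, y, lambda_grid = 0)
  expect_equal(f0$beta, fit_ols(X, y), tolerance = 1e-10)

  Q <- qr.Q(qr(matrix(rnorm(40 * 6), 40, 6)))  # orthonormal columns
  b_ols <- fit_ols(Q, y)
  for (lam in c(0.5, 2, 10)) {
    f <- fit_ridge(Q, y, lambda_grid = lam)
    expect_equal(f$beta, b_ols / (1 + lam), tolerance = 1e-10)
  }
  expect_error(fit_ridge(X, y, lambda_grid = c(1, -1)),
               class = "respgate_parameter_error")
  expect_error(fit_ridge(X, y, lambda_grid = numeric(0)),
               class = "respgate_parameter_error")
})

test_that("closed-form LOOCV matches explicit leave-one-out refits", {
  set.seed(5)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- drop(X %*% rnorm(5)) + rnorm(30, sd = 0.5)
  grid <- c(0.01, 0.1, 1, 10)
  f <- fit_ridge(X, y, lambda_grid = grid)
  explicit <- vapply(grid, function(l) loocv_explicit(X, y, l), numeric(1))
  expect_equal(f$cv$loocv, explicit, tolerance = 1e-8)
  expect_equal(f$lambda, grid[which.min(explicit)])
})

test_that("ridge coefficient norm is non-increasing along the penalty path", {
  set.seed(6)
  X <- matrix(rnorm(60 * 10), 60, 10)
  y <- rnorm(60)
  norms <- vapply(c(0, 0.1, 1, 10, 100, 1000), function(l)
    sqrt(sum(fit_ridge(X, y, lambda_grid = l)$beta^2)), numeric(1))
  expect_true(all(diff(norms) <= 1e-12))
})

test_that("ADMM lasso matches OLS at zero penalty and vanishes above lambda_max", {
  set.seed(7)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- rnorm(40)
  expect_equal(as.numeric(admm_lasso(X, y, 0)), fit_ols(X, y),
               tolerance = 1e-6)
  lmax <- lasso_lambda_max(X, y)
  expect_identical(as.numeric(admm_lasso(X, y, lmax)), rep(0, 10))
  expect_identical(as.numeric(admm_lasso(X, y, 2 * lmax)), rep(0, 10))
})

test_that("ADMM lasso agrees with an ISTA oracle and with glmnet", {
  set.seed(8)
  X <- matrix(rnorm(40 * 10), 40, 10)
  y <- drop(X %*% c(2, -1.5, rep(0, 8))) + rnorm(40, sd = 0.3)
  lam <- 0.1 * lasso_lambda_max(X, y)
  b <- as.numeric(admm_lasso(X, y, lam, tol = 1e-10))
  expect_lt(max(abs(b - ista_lasso(X, y, lam))), 1e-5)
  skip_if_not_installed("glmnet")
  g <- glmnet::glmnet(X, y, alpha = 1, lambda = lam / nrow(X),
                      intercept = FALSE, standardize = FALSE,
                      thresh = 1e-14)
  expect_lt(max(abs(b - as.numeric(g$beta))), 1e-4)
})

test_that("lasso L1 norm is non-increasing in the penalty", {
  set.seed(9)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- rnorm(50)
  lmax <- lasso_lambda_max(X, y)
  l1 <- vapply(lmax * c(0.01, 0.05, 0.2, 0.5, 1), function(l)
    sum(abs(admm_lasso(X, y, l))), numeric(1))
  expect_true(all(diff(l1) <= 1e-8))
})

test_that("ADMM flags non-convergence without raising an error", {
  set.seed(10)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  expect_warning(
    b <- admm_lasso(X, y, 0.05 * lasso_lambda_max(X, y), max_iter = 2L),
    "did not converge")
  expect_false(attr(b, "converged"))
})

test_that("GCV selection recomputes the published formula and recovers sparse truth", {
  set.seed(11)
  X <- matrix(rnorm(200 * 15), 200, 15)
  b_star <- c(3, -2, 1.5, rep(0, 12))
  y <- drop(X %*% b_star) + rnorm(200, sd = 0.1)
  f <- fit_l2l1(X, y)
  N <- nrow(X)
  for (i in seq_len(nrow(f$cv))) {
    b <- admm_lasso(X, y, f$cv$lambda[i])
    rss <- sum((y - drop(X %*% b))^2)
    df <- sum(b != 0)
    expect_equal(f$cv$gcv[i], N * rss / (N - df)^2, tolerance = 1e-10)
  }
  expect_true(all(which(b_star != 0) %in% which(f$beta != 0)))
})

test_that("single-candidate GCV at zero penalty equals OLS", {
  set.seed(12)
  X <- matrix(rnorm(40 * 6), 40, 6)
  y <- rnorm(40)
  f <- fit_l2l1(X, y, lambda_grid = 0)
  expect_equal(f$beta, fit_ols(X, y), tolerance = 1e-6)
})

test_that("predict_pair computes the two inner products", {
  ws <- make_windows(test_trace(duration = 40, seed = 2), m = 15, J = 3)
  model <- fit_predictor(ws, "ols", horizon_j = 3)
  x <- as.numeric(ws$inputs[5, ])
  p <- predict_pair(model, x)
  expect_equal(unname(p["prev"]), sum(x * model$beta_prev), tolerance = 1e-12)
  expect_equal(unname(p["last"]), sum(x * model$beta_last), tolerance = 1e-12)
  expect_equal(unname(predict_pair(model, numeric(15))), c(0, 0))
  expect_error(predict_pair(model, numeric(10)),
               class = "respgate_input_error")

  dummy <- fit_predictor(ws, "dummy", horizon_j = 3)
  expect_equal(unname(predict_pair(dummy, x)), c(x[15], x[15]))
})

test_that("the Kalman filter is exact on ramps, constants, and matches a scalar reference", {
  dt <- 0.2
  ramp <- 2 + 1.5 * (0:80) * dt
  expect_equal(kalman_predict(ramp, dt, 0.6), ramp[81] + 1.5 * 0.6,
               tolerance = 1e-6)
  expect_equal(kalman_predict(rep(5, 60), dt, 0.4), 5, tolerance = 1e-9)

  tt <- (0:149) * dt
  y <- 10 + 5 * sin(2 * pi * tt / 4)
  ref <- kalman_scalar_reference(y, dt, q = 10, r = 0.1)
  expect_equal(kalman_predict(y, dt, 0.6),
               ref$pos[150] + ref$vel[150] * 0.6, tolerance = 1e-9)
  expect_error(kalman_predict(1, dt, 0.4), class = "respgate_input_error")
})

test_that("models survive a JSON round-trip", {
  ws <- make_windows(test_trace(duration = 40, seed = 13), m = 15, J = 3)
  model <- fit_predictor(ws, "ridge", horizon_j = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_equal(back$beta_prev, model$beta_prev)
  expect_equal(back$beta_last, model$beta_last)
  expect_identical(back$method, model$method)
  expect_identical(back$horizon_j, model$horizon_j)
})
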