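#' Ordinary least squares without intercept
#'
#' Minimizes the residual sum of squares of `labels - inputs %*% beta`. The
#' forecasting model is a pure inner product of the input window with a
#' coefficient vector, so no intercept is fitted. Rank-deficient problems
#' return the minimum-norm solution (via the singular value decomposition),
#' which makes the fit deterministic.
#'
#' @param inputs N x m numeric matrix of input windows.
#' @param labels Length-N numeric vector of future samples.
#' @return Length-m coefficient vector.
#' @examples
#' fit_ols(matrix(1:3), c(2, 4, 6))  # slope 2
#' @export
fit_ols <- function(inputs, labels) {
  X <- as.matrix(inputs)
  y <- as.numeric(labels)
  if (length(y) == 0L || nrow(X) == 0L)
    abort("empty input.", class = "respgate_input_error")
  if (nrow(X) != length(y))
    abort("`inputs` rows and `labels` length differ.",
          class = "respgate_input_error")
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d, 0)
  r <- sum(s$d > tol)
  if (r == 0L) return(numeric(ncol(X)))
  drop(s$v[, seq_len(r), drop = FALSE] %*%
         (crossprod(s$u[, seq_len(r), drop = FALSE], y) / s$d[seq_len(r)]))
}

#' Default regularization grid for ridge regression
#' @param n Number of grid points.
#' @return Log-spaced penalties in `[1e-4, 1e2]`.
#' @export
ridge_lambda_grid <- function(n = 20L) 10^seq(-4, 2, length.out = n)

#' Ridge regression with closed-form leave-one-out cross-validation
#'
#' For each candidate penalty the leave-one-out cross-validation (LOOCV)
#' error is computed without refitting, via the leverage identity
#' `e_i / (1 - h_ii)` applied to the ridge hat matrix; the returned
#' coefficients correspond to the penalty minimizing LOOCV error.
#'
#' @inheritParams fit_ols
#' @param lambda_grid Non-negative candidate penalties (`0` reduces to OLS).
#' @return List with `beta` (length-m vector), `lambda` (chosen penalty) and
#'   `cv` (tibble of `lambda`, `loocv`).
#' @export
fit_ridge <- function(inputs, labels, lambda_grid = ridge_lambda_grid()) {
  X <- as.matrix(inputs)
  y <- as.numeric(labels)
  if (length(lambda_grid) == 0L)
    abort("`lambda_grid` must be non-empty.",
          class = "respgate_parameter_error")
  if (any(lambda_grid < 0))
    abort("ridge penalties must be non-negative.",
          class = "respgate_parameter_error")
  if (nrow(X) != length(y) || length(y) == 0L)
    abort("`inputs` rows and `labels` length differ or empty.",
          class = "respgate_input_error")
  s <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * max(s$d, 0)
  uy <- crossprod(s$u, y)                       # t(U) y, length k
  loocv <- vapply(lambda_grid, function(lam) {
    # filter factors d^2/(d^2+lam); at lam = 0 keep only numerically
    # nonzero singular values (minimum-norm OLS limit)
    f <- if (lam == 0) as.numeric(s$d > tol) else s$d^2 / (s$d^2 + lam)
    fitted <- drop(s$u %*% (f * uy))
    h <- drop((s$u^2) %*% f)                    # leverages diag(H)
    r <- (y - fitted) / pmax(1 - h, .Machine$double.eps)
    mean(r^2)
  }, numeric(1))
  lam <- lambda_grid[which.min(loocv)]
  f <- if (lam == 0) ifelse(s$d > tol, 1 / s$d, 0) else s$d / (s$d^2 + lam)
  beta <- drop(s$v %*% (f * uy))
  list(beta = beta, lambda = lam,
       cv = tibble(lambda = lambda_grid, loocv = loocv))
}

#' Largest useful lasso penalty
#'
#' Smallest penalty for which the L2-L1 solution of
#' `0.5 * ||y - X b||^2 + lambda * ||b||_1` is exactly zero:
#' `max |X' y|`.
#'
#' @inheritParams fit_ols
#' @return Scalar penalty.
#' @export
lasso_lambda_max <- function(inputs, labels)
  max(abs(crossprod(as.matrix(inputs), as.numeric(labels))))

soft_threshold <- function(x, k) sign(x) * pmax(abs(x) - k, 0)

#' L2-L1 (lasso) regression solved by ADMM
#'
#' Minimizes `0.5 * ||y - X b||^2 + lambda * ||b||_1` by the alternating
#' direction method of multipliers: a ridge-like primal update, a
#' soft-thresholding update of the split variable, and a dual ascent step.
#' Iterations stop when both the primal residual `||b - z||` and the dual
#' residual `rho * ||z - z_prev||` fall below `tol`.
#'
#' @inheritParams fit_ols
#' @param lambda Non-negative L1 penalty.
#' @param rho ADMM penalty parameter; the default `max(1, lambda / 10)`
#'   keeps the splitting step on the scale of the penalty, which converges
#'   fast across the whole penalty grid. Any positive value reaches the same
#'   optimum.
#' @param tol Residual-norm stopping tolerance.
#' @param max_iter Iteration cap; on hitting it the result carries
#'   `attr(, "converged") = FALSE` and a warning is raised (not an error).
#' @return Length-m coefficient vector (exactly sparse), with attributes
#'   `converged` and `iterations`.
#' @export
admm_lasso <- function(inputs, labels, lambda, rho = NULL,
                       tol = 1e-8, max_iter = 10000L) {
  X <- as.matrix(inputs)
  y <- as.numeric(labels)
  stopifnot_scalar_num(lambda, "lambda", 0)
  if (is.null(rho)) rho <- max(1, lambda / 10)
  stopifnot_scalar_num(rho, "rho", 0, strict = TRUE)
  if (nrow(X) != length(y) || length(y) == 0L)
    abort("`inputs` rows and `labels` length differ or empty.",
          class = "respgate_input_error")
  m <- ncol(X)
  if (lambda == 0) {
    beta <- fit_ols(X, y)
    attr(beta, "converged") <- TRUE
    attr(beta, "iterations") <- 0L
    return(beta)
  }
  Xty <- drop(crossprod(X, y))
  R <- chol(crossprod(X) + diag(rho, m))
  z <- numeric(m)
  u <- numeric(m)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    b <- backsolve(R, backsolve(R, Xty + rho * (z - u), transpose = TRUE))
    z_old <- z
    z <- soft_threshold(b + u, lambda / rho)
    u <- u + b - z
    if (sqrt(sum((b - z)^2)) < tol && rho * sqrt(sum((z - z_old)^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warn(sprintf("ADMM did not converge in %d iterations.", max_iter))
  beta <- z                    # the split variable is exactly sparse
  attr(beta, "converged") <- converged
  attr(beta, "iterations") <- it
  beta
}

#' Default penalty grid for the L2-L1 model
#' @inheritParams fit_ols
#' @param n Number of grid points.
#' @return Decreasing fractions of [lasso_lambda_max()], log-spaced over
#'   three decades.
#' @export
lasso_lambda_grid <- function(inputs, labels, n = 15L)
  lasso_lambda_max(inputs, labels) * 10^seq(0, -3, length.out = n)

#' L2-L1 regression with penalty chosen by generalized cross-validation
#'
#' Fits [admm_lasso()] over a penalty grid and selects the penalty minimizing
#' the generalized cross-validation score
#' `GCV(lambda) = N * RSS(lambda) / (N - df(lambda))^2`, with the effective
#' degrees of freedom `df` taken as the number of nonzero coefficients (the
#' conventional unbiased estimate for the lasso). Saturated fits
#' (`df = N`) are skipped with a warning.
#'
#' @inheritParams fit_ols
#' @param lambda_grid Candidate penalties; default [lasso_lambda_grid()].
#' @param ... Passed to [admm_lasso()].
#' @return List with `beta`, `lambda` and `cv` (tibble of `lambda`, `df`,
#'   `rss`, `gcv`).
#' @export
fit_l2l1 <- function(inputs, labels, lambda_grid = NULL, ...) {
  X <- as.matrix(inputs)
  y <- as.numeric(labels)
  if (is.null(lambda_grid)) lambda_grid <- lasso_lambda_grid(X, y)
  if (length(lambda_grid) == 0L)
    abort("`lambda_grid` must be non-empty.",
          class = "respgate_parameter_error")
  N <- length(y)
  fits <- map(lambda_grid, function(lam) admm_lasso(X, y, lam, ...))
  cv <- tibble(
    lambda = lambda_grid,
    df = map_dbl(fits, ~ sum(.x != 0)),
    rss = map_dbl(fits, ~ sum((y - drop(X %*% .x))^2))
  )
  cv$gcv <- ifelse(cv$df >= N, NA_real_, N * cv$rss / (N - cv$df)^2)
  if (anyNA(cv$gcv))
    warn("skipping saturated fits (df = N) in GCV selection.")
  if (all(is.na(cv$gcv)))
    abort("all candidate penalties give saturated fits.",
          class = "respgate_parameter_error")
  best <- which.min(cv$gcv)
  beta <- as.numeric(fits[[best]])
  list(beta = beta, lambda = lambda_grid[best], cv = cv)
}

#' Fit a two-horizon linear prediction model on a window set
#'
#' Fits the coefficient vectors `beta_prev` and `beta_last` that map an input
#' window to the forecasts at horizons `j - 1` and `j` samples ahead (0.4 s
#' and 0.6 s for `j = 3` at 5 Hz). The two vectors are fitted independently,
#' one per label column. The `dummy` method is the persistence model (both
#' coefficient vectors select the window's last sample).
#'
#' @param ws A `window_set` from [make_windows()] (typically the training
#'   split).
#' @param method `"ols"`, `"ridge"`, `"l2l1"` or `"dummy"`.
#' @param horizon_j Horizon index `j` (2 for a 0.4 s window, 3 for 0.6 s at
#'   5 Hz sampling).
#' @param lambda_grid Optional penalty grid for `"ridge"`/`"l2l1"`.
#' @return A `predictor_model` with elements `beta_prev`, `beta_last`,
#'   `horizon_j`, `lambda` (0 for OLS/dummy), `method`, `m`, `dt`, `n_train`.
#' @export
fit_predictor <- function(ws, method = c("ols", "ridge", "l2l1", "dummy"),
                          horizon_j = 3L, lambda_grid = NULL) {
  method <- match.arg(method)
  if (!inherits(ws, "window_set"))
    abort("`ws` must be a window_set.", class = "respgate_input_error")
  horizon_j <- as.integer(horizon_j)
  if (horizon_j < 2L || horizon_j > ws$J)
    abort(sprintf("`horizon_j` must lie in 2..%d.", ws$J),
          class = "respgate_parameter_error")
  y_prev <- ws$labels[, horizon_j - 1L]
  y_last <- ws$labels[, horizon_j]
  lam <- 0
  if (method == "ols") {
    beta_prev <- fit_ols(ws$inputs, y_prev)
    beta_last <- fit_ols(ws$inputs, y_last)
  } else if (method == "ridge") {
    grid <- lambda_grid %||% ridge_lambda_grid()
    fp <- fit_ridge(ws$inputs, y_prev, grid)
    fl <- fit_ridge(ws$inputs, y_last, grid)
    beta_prev <- fp$beta; beta_last <- fl$beta
    lam <- c(prev = fp$lambda, last = fl$lambda)
  } else if (method == "l2l1") {
    fp <- if (is.null(lambda_grid)) fit_l2l1(ws$inputs, y_prev)
          else fit_l2l1(ws$inputs, y_prev, lambda_grid)
    fl <- if (is.null(lambda_grid)) fit_l2l1(ws$inputs, y_last)
          else fit_l2l1(ws$inputs, y_last, lambda_grid)
    beta_prev <- fp$beta; beta_last <- fl$beta
    lam <- c(prev = fp$lambda, last = fl$lambda)
  } else {                               # dummy / persistence
    beta_prev <- beta_last <- c(numeric(ws$m - 1L), 1)
  }
  new_predictor_model(beta_prev, beta_last, horizon_j, lam, method,
                      m = ws$m, dt = ws$dt, n_train = n_windows(ws))
}

new_predictor_model <- function(beta_prev, beta_last, horizon_j, lambda,
                                method, m, dt, n_train) {
  structure(
    list(beta_prev = as.numeric(beta_prev), beta_last = as.numeric(beta_last),
         horizon_j = horizon_j, lambda = lambda, method = method,
         m = m, dt = dt, n_train = n_train),
    class = "predictor_model"
  )
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf(
    "<predictor_model> %s, j = %d (%.1f s ahead), m = %d, n_train = %d\n",
    x$method, x$horizon_j, x$horizon_j * x$dt, x$m, x$n_train))
  invisible(x)
}

#' @export
tidy.predictor_model <- function(x, ...) {
  tibble(
    term = rep(paste0("lag_", (x$m - 1L):0L), 2L),
    horizon = rep(c(x$horizon_j - 1L, x$horizon_j), each = x$m),
    estimate = c(x$beta_prev, x$beta_last)
  )
}

#' @export
glance.predictor_model <- function(x, ...) {
  tibble(method = x$method, horizon_j = x$horizon_j, m = x$m,
         lambda = max(x$lambda), n_train = x$n_train)
}

#' Two-horizon prediction from one input window
#'
#' Inner products of the window with the model's two coefficient vectors.
#'
#' @param model A `predictor_model`.
#' @param x Length-m numeric input window (oldest sample first).
#' @return Named numeric vector `c(prev = , last = )` in mm: the forecasts at
#'   horizons `j - 1` and `j` samples ahead.
#' @export
predict_pair <- function(model, x) {
  if (!inherits(model, "predictor_model"))
    abort("`model` must be a predictor_model.",
          class = "respgate_input_error")
  x <- as.numeric(x)
  if (length(x) != model$m)
    abort(sprintf("window length %d, expected m = %d.",
                  length(x), model$m),
          class = "respgate_input_error")
  c(prev = sum(x * model$beta_prev), last = sum(x * model$beta_last))
}

#' Predictions for every window in a window set
#'
#' @param model A `predictor_model`.
#' @param ws A `window_set` with the same `m`.
#' @return Tibble with `time` (anchor time), `y_prev`, `y_last` (mm): the
#'   prediction stream consumed by [generate_gating()].
#' @export
predict_windows <- function(model, ws) {
  if (!inherits(ws, "window_set"))
    abort("`ws` must be a window_set.", class = "respgate_input_error")
  if (ws$m != model$m)
    abort("window length mismatch between model and window set.",
          class = "respgate_input_error")
  tibble(
    time = ws$anchor_times,
    y_prev = drop(ws$inputs %*% model$beta_prev),
    y_last = drop(ws$inputs %*% model$beta_last)
  )
}

#' Oracle prediction stream (true future samples)
#'
#' Returns the stream a perfect predictor would emit: the true trace values
#' at horizons `j - 1` and `j` samples beyond each window anchor. Used to
#' establish the best-case bound of the gating pipeline.
#'
#' @param ws A `window_set` whose labels cover horizon `horizon_j`.
#' @param horizon_j Horizon index `j`.
#' @return Tibble `time`, `y_prev`, `y_last`.
#' @export
oracle_stream <- function(ws, horizon_j = 3L) {
  if (!inherits(ws, "window_set"))
    abort("`ws` must be a window_set.", class = "respgate_input_error")
  horizon_j <- as.integer(horizon_j)
  if (horizon_j < 2L || horizon_j > ws$J)
    abort(sprintf("`horizon_j` must lie in 2..%d.", ws$J),
          class = "respgate_parameter_error")
  tibble(time = ws$anchor_times,
         y_prev = ws$labels[, horizon_j - 1L],
         y_last = ws$labels[, horizon_j])
}

#' Constant-velocity Kalman filter prediction
#'
#' Baseline predictor: a position-velocity state-space model with
#' white-noise-acceleration process noise, filtered over the observed
#' segment and extrapolated `horizon` seconds beyond the last sample.
#'
#' @param y Numeric vector of observed positions (mm), uniformly sampled.
#' @param dt Sampling period (s).
#' @param horizon Extrapolation span beyond the last sample (s).
#' @param q Process-noise spectral density (mm^2/s^3).
#' @param r Measurement-noise variance (mm^2).
#' @return Predicted position (mm) at `horizon` s past the last sample.
#' @export
kalman_predict <- function(y, dt, horizon, q = 10, r = 0.1) {
  st <- kalman_filter_cv(y, dt, q, r)
  n <- length(y)
  st$pos[n] + st$vel[n] * horizon
}

# constant-velocity Kalman filter; returns filtered position/velocity series
kalman_filter_cv <- function(y, dt, q = 10, r = 0.1) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 2L)
    abort("Kalman filter needs at least 2 samples.",
          class = "respgate_input_error")
  A <- matrix(c(1, 0, dt, 1), 2, 2)
  Q <- q * matrix(c(dt^3 / 3, dt^2 / 2, dt^2 / 2, dt), 2, 2)
  H <- matrix(c(1, 0), 1, 2)
  x <- c(y[1L], (y[2L] - y[1L]) / dt)
  P <- diag(c(r, 2 * r / dt^2))
  pos <- vel <- numeric(n)
  pos[1L] <- x[1L]; vel[1L] <- x[2L]
  for (k in 2:n) {
    x <- A %*% x
    P <- A %*% P %*% t(A) + Q
    S <- drop(H %*% P %*% t(H)) + r
    K <- (P %*% t(H)) / S
    x <- x + K * drop(y[k] - H %*% x)
    P <- (diag(2) - K %*% H) %*% P
    pos[k] <- x[1L]; vel[k] <- x[2L]
  }
  list(pos = pos, vel = vel)
}

#' Kalman-filter prediction stream over a trace channel
#'
#' Runs the constant-velocity filter once over the channel and, at each
#' anchor time from `start_time` on, extrapolates the filtered state to the
#' two horizons `((j-1) * dt, j * dt)`.
#'
#' @param trace Trace data frame.
#' @param channel Channel name.
#' @param horizon_j Horizon index `j`.
#' @param start_time First anchor time to emit (s).
#' @inheritParams kalman_predict
#' @return Tibble `time`, `y_prev`, `y_last`.
#' @export
kalman_stream <- function(trace, channel = "si", horizon_j = 3L,
                          start_time = 0, q = 10, r = 0.1) {
  assert_trace(trace, channel)
  dt <- trace_dt(trace)
  st <- kalman_filter_cv(trace[[channel]], dt, q, r)
  keep <- trace$time >= start_time
  tibble(
    time = trace$time[keep],
    y_prev = st$pos[keep] + st$vel[keep] * (horizon_j - 1L) * dt,
    y_last = st$pos[keep] + st$vel[keep] * horizon_j * dt
  )
}

#' Save / load a predictor model as JSON
#'
#' @param model A `predictor_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` returns
#'   the restored `predictor_model`.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "predictor_model"))
    abort("`model` must be a predictor_model.",
          class = "respgate_input_error")
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_predictor_model(x$beta_prev, x$beta_last, as.integer(x$horizon_j),
                      x$lambda, x$method, as.integer(x$m), x$dt,
                      as.integer(x$n_train))
}
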