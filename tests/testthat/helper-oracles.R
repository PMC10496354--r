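# Independent reference implementations used as oracles. These deliberately
# take the slow/explicit route (normal equations, explicit refits, proximal
# gradient, scalar Kalman algebra, dense resampling) so they share no code
# with the package's implementations.

# OLS via explicit normal equations
ols_normal_equations <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# ridge LOOCV by explicitly refitting N times
loocv_explicit <- function(X, y, lambda) {
  n <- nrow(X)
  errs <- vapply(seq_len(n), function(i) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    b <- solve(crossprod(Xi) + diag(lambda, ncol(X)), crossprod(Xi, yi))
    (y[i] - drop(X[i, ] %*% b))^2
  }, numeric(1))
  mean(errs)
}

# lasso (0.5*RSS + lambda*L1) by proximal gradient (ISTA), run to high
# precision
ista_lasso <- function(X, y, lambda, tol = 1e-10, max_iter = 2e5) {
  L <- max(eigen(crossprod(X), symmetric = TRUE,
                 only.values = TRUE)$values)
  st <- 1 / L
  b <- numeric(ncol(X))
  Xty <- drop(crossprod(X, y))
  XtX <- crossprod(X)
  for (k in seq_len(max_iter)) {
    g <- b + st * (Xty - drop(XtX %*% b))
    b_new <- sign(g) * pmax(abs(g) - st * lambda, 0)
    if (max(abs(b_new - b)) < tol) return(b_new)
    b <- b_new
  }
  b
}

# constant-velocity Kalman filter in explicit scalar algebra
kalman_scalar_reference <- function(y, dt, q, r) {
  n <- length(y)
  p <- y[1]
  v <- (y[2] - y[1]) / dt
  p11 <- r; p12 <- 0; p22 <- 2 * r / dt^2
  q11 <- q * dt^3 / 3; q12 <- q * dt^2 / 2; q22 <- q * dt
  pos <- vel <- numeric(n)
  pos[1] <- p; vel[1] <- v
  for (k in 2:n) {
    # predict
    p <- p + dt * v
    n11 <- p11 + dt * p12 + dt * (p12 + dt * p22) + q11
    n12 <- p12 + dt * p22 + q12
    n22 <- p22 + q22
    # update
    s <- n11 + r
    k1 <- n11 / s; k2 <- n12 / s
    innov <- y[k] - p
    p <- p + k1 * innov
    v <- v + k2 * innov
    p11 <- (1 - k1) * n11
    p12 <- (1 - k1) * n12
    p22 <- n22 - k2 * n12
    pos[k] <- p; vel[k] <- v
  }
  list(pos = pos, vel = vel)
}

# threshold crossings by dense linear resampling (1 kHz) and sign scan
crossings_dense_oracle <- function(time, y, th, fs = 1000) {
  grid <- seq(min(time), max(time), by = 1 / fs)
  yi <- stats::approx(time, y, xout = grid)$y
  s <- yi - th
  k <- which(s[-length(s)] * s[-1] < 0)
  tc <- grid[k] + (1 / fs) * s[k] / (s[k] - s[k + 1])
  dir <- ifelse(s[k + 1] < 0, "on", "off")
  data.frame(time = tc, direction = dir)
}

# exact two-sided signed-rank p-value by enumerating all sign assignments
# (no ties, no zeros), mirroring the doubled-smaller-tail convention
wilcoxon_exact_enumeration <- function(a, b) {
  d <- a - b
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- drop(signs %*% rk)
  lower <- mean(v_all <= v_obs)
  upper <- mean(v_all >= v_obs)
  if (v_obs > n * (n + 1) / 4) min(1, 2 * upper) else min(1, 2 * lower)
}

# short deterministic test trace
test_trace <- function(duration = 120, seed = 11, mean_period = 4, ...) {
  simulate_trace(breathing_params(mean_period = mean_period,
                                  duration = duration, seed = seed, ...))
}
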