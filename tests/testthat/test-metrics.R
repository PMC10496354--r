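test_that("amplitude metrics match their defining formulas", {
  y <- c(1, 2, 3, 4)
  expect_equal(mae(y, y), 0)
  expect_equal(rmse(y, y), 0)
  expect_equal(rsq(y, y), 1)
  expect_equal(mae(c(0, 0, 0, 0), c(1, -1, 1, -1)), 1)
  expect_equal(rmse(c(0, 0, 0, 0), c(1, -1, 1, -1)), 1)
  set.seed(41)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(mae(a, b), mean(abs(a - b)), tolerance = 1e-12)
  expect_equal(rmse(a, b), sqrt(mean((a - b)^2)), tolerance = 1e-12)
  expect_equal(rsq(a, b),
               1 - sum((a - b)^2) / sum((a - mean(a))^2), tolerance = 1e-12)
  expect_warning(out <- rsq(rep(2, 5), rnorm(5)), "zero variance")
  expect_true(is.na(out))
  expect_error(mae(1:3, 1:4), class = "respgate_input_error")
})

test_that("MAE never exceeds RMSE and R2 is 1 only for perfect predictions", {
  set.seed(42)
  for (k in 1:1000) {
    n <- sample(3:30, 1)
    y <- rnorm(n); yh <- rnorm(n)
    expect_lte(mae(y, yh), rmse(y, yh) + 1e-12)
  }
  y <- rnorm(50)
  expect_identical(rsq(y, y), 1)
  expect_lt(rsq(y, y + rnorm(50, sd = 0.1)), 1)
})

test_that("crossing errors pair events one-to-one by direction", {
  ev <- tibble::tibble(time = c(2, 4.1, 6.2, 8.0),
                       direction = c("on", "off", "on", "off"))
  same <- crossing_errors(ev, ev, pairing_window = 2)
  expect_equal(same$error_ms, rep(0, 4))
  shifted <- ev; shifted$time <- ev$time + 0.08
  ce <- crossing_errors(shifted, ev, pairing_window = 2)
  expect_equal(ce$error_ms, rep(80, 4), tolerance = 1e-9)
})

test_that("nearest matching agrees with an exhaustive bipartite oracle", {
  set.seed(43)
  ref_on <- seq(2, 118, by = 4)
  ref <- tibble::tibble(time = sort(c(ref_on, ref_on + 1.7)),
                        direction = rep(c("on", "off"), length(ref_on)))
  pred <- ref
  pred$time <- pred$time + rnorm(nrow(ref), sd = 0.05)
  ce <- crossing_errors(pred, ref, pairing_window = 2)
  expect_identical(nrow(ce), nrow(ref))
  # oracle: all direction-respecting one-to-one assignments on each block;
  # with jitter << spacing the identity assignment is uniquely optimal
  for (d in c("on", "off")) {
    p <- sort(pred$time[pred$direction == d])
    r <- sort(ref$time[ref$direction == d])
    got <- ce[ce$direction == d, ]
    got <- got[order(got$ref_time), ]
    expect_equal(got$ref_time, r)
    expect_equal(got$pred_time, p)
  }
})

test_that("gating errors reproduce constructed offsets and the latency bound", {
  cfg <- gating_config(threshold = 10)
  ev <- tibble::tibble(time = c(10, 12, 14, 16, 18, 20),
                       direction = rep(c("on", "off"), 3))
  ideal <- ideal_gating(ev, cfg, span = c(0, 25))
  # the no-prediction controller is late by exactly the latency
  dummy <- crossing_time_gating(ev, cfg, span = c(0, 25))
  ge <- gating_errors(dummy, ideal, pairing_window = 1.9)
  expect_equal(ge$error_ms, rep(500, 6))
  # constructed +/- (20, 40, 60) ms offsets average to 40 ms
  off <- ideal
  off$time <- off$time + c(0.02, -0.04, 0.06, -0.02, 0.04, -0.06)
  ge2 <- gating_errors(off, ideal, pairing_window = 1)
  expect_equal(mean(ge2$error_ms), 40, tolerance = 1e-9)
})

test_that("gating accuracy is exact, symmetric and maximal on identical signals", {
  cfg <- gating_config(threshold = 10)
  ev <- tibble::tibble(time = c(10, 12, 14), direction = c("on", "off", "on"))
  sig <- ideal_gating(ev, cfg, span = c(0, 100))
  expect_equal(gating_accuracy(sig, sig), 100)
  # always-off vs 30 s beam-on over 100 s -> 70%
  on30 <- ideal_gating(tibble::tibble(time = c(10, 40),
                                      direction = c("on", "off")),
                       cfg, span = c(0, 100))
  off_sig <- generate_gating(tibble::tibble(time = numeric(0),
                                            y_prev = numeric(0),
                                            y_last = numeric(0)),
                             cfg, span = c(0, 100), initial_state = 0L)
  expect_equal(gating_accuracy(off_sig, on30, span = c(0, 100)), 70)
  expect_equal(gating_accuracy(on30, off_sig, span = c(0, 100)), 70)
})

test_that("exact overlap agrees with a 1 ms discretized oracle on random signals", {
  set.seed(44)
  random_signal <- function() {
    n <- sample(5:15, 1)
    times <- sort(runif(n, 0, 100))
    ideal_gating(tibble::tibble(time = times,
                                direction = rep(c("on", "off"),
                                                length.out = n)),
                 gating_config(threshold = 0), span = c(0, 100))
  }
  for (k in 1:5) {
    s1 <- random_signal(); s2 <- random_signal()
    acc <- gating_accuracy(s1, s2, span = c(0, 100))
    grid <- seq(0.0005, 99.9995, by = 0.001)
    acc_oracle <- 100 * mean(signal_state_at(s1, grid) ==
                               signal_state_at(s2, grid))
    expect_lt(abs(acc - acc_oracle), 0.1)
  }
})

test_that("the Wilcoxon comparison matches exact enumeration and is symmetric", {
  a <- c(12.1, 9.8, 11.4, 10.2, 13.0, 9.1)
  b <- c(11.0, 10.3, 10.1, 9.4, 11.8, 8.7)
  p <- compare_models(a, b)
  expect_equal(p, wilcoxon_exact_enumeration(a, b), tolerance = 1e-12)
  expect_equal(compare_models(b, a), p, tolerance = 1e-12)
  expect_warning(out <- compare_models(a, a), "degenerate")
  expect_true(is.na(out))
  expect_error(compare_models(1:3, 4:6), class = "respgate_input_error")
})
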