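test_that("the burn-in threshold is the channel mean over the burn-in window", {
  tr <- tibble::tibble(time = (0:99) * 0.2, si = rep(7.5, 100))
  expect_equal(estimate_threshold(tr, 10), 7.5)
  tr2 <- test_trace(duration = 60, seed = 31)
  keep <- tr2$time < 30
  expect_equal(estimate_threshold(tr2, 30), mean(tr2$si[keep]),
               tolerance = 1e-12)
  expect_error(estimate_threshold(tr2, 0), class = "respgate_input_error")
})

test_that("crossing interpolation hits the exact endpoints and midpoint", {
  # threshold equal to the later prediction: crossing at the j-horizon
  t1 <- predicted_crossing_time(5, 10, 10, t_i = 0, horizon_j = 3)
  expect_equal(as.numeric(t1), 0.6)
  # threshold equal to the earlier prediction: crossing at (j-1) horizon
  t2 <- predicted_crossing_time(5, 10, 5, t_i = 0, horizon_j = 3)
  expect_equal(as.numeric(t2), 0.4)
  # midpoint by linearity
  t3 <- predicted_crossing_time(5, 10, 7.5, t_i = 0, horizon_j = 3)
  expect_equal(as.numeric(t3), 0.5)
  # flat pair at the threshold: tie rule returns the earlier horizon time
  t4 <- predicted_crossing_time(5, 5, 5, t_i = 2, horizon_j = 3)
  expect_equal(as.numeric(t4), 2.4)
  # flat pair away from the threshold: no crossing
  expect_true(is.na(predicted_crossing_time(5, 5, 7, t_i = 0)))
  # out-of-range extrapolation: no crossing
  expect_true(is.na(predicted_crossing_time(5, 6, 9, t_i = 0)))
  # extrapolated crossing within the pre-trigger margin
  t5 <- predicted_crossing_time(5, 7, 7.5, t_i = 0, horizon_j = 3)
  expect_equal(as.numeric(t5), 0.65)
  expect_identical(attr(t5, "condition"), "extrapolated")
})

test_that("the published crossing formula equals standard linear interpolation", {
  set.seed(32)
  n <- 1e4
  y0 <- rnorm(n, 10, 5)
  y1 <- rnorm(n, 10, 5)
  th <- y0 + runif(n) * (y1 - y0)        # always bracketed
  ti <- runif(n, 0, 300)
  dt <- 0.2
  for (j in c(2L, 3L)) {
    got <- vapply(seq_len(n), function(i)
      as.numeric(predicted_crossing_time(y0[i], y1[i], th[i], ti[i],
                                         horizon_j = j)), numeric(1))
    standard <- ti + (j - 1) * dt + dt * (th - y0) / (y1 - y0)
    expect_lt(max(abs(got - standard)), 1e-10)
  }
})

test_that("reference crossings of a sinusoid land at its analytic threshold times", {
  tt <- (0:300) * 0.2
  tr <- tibble::tibble(time = tt, si = 10 + 5 * sin(2 * pi * tt / 4))
  ev <- reference_crossings(tr, 10)
  analytic <- seq(0, 60, by = 2)[-1]   # t = 2, 4, ... (t = 0 touches only)
  matched <- vapply(ev$time[ev$time > 0.5], function(t)
    min(abs(t - analytic)), numeric(1))
  expect_lt(max(matched), 0.015)       # interpolation bias is O(dt^2)
  expect_true(all(ev$direction[-1] != ev$direction[-nrow(ev)]))  # alternate
  # constant trace: no crossings
  expect_identical(
    nrow(reference_crossings(tibble::tibble(time = tt, si = rep(1, 301)), 1)),
    0L)
})

test_that("reference crossings agree with a dense-resampling oracle", {
  tr <- test_trace(duration = 80, seed = 33, noise_sd = 0)
  th <- estimate_threshold(tr, 30)
  ev <- reference_crossings(tr, th)
  oracle <- crossings_dense_oracle(tr$time, tr$si, th)
  expect_equal(nrow(ev), nrow(oracle))
  expect_lt(max(abs(ev$time - oracle$time)), 5e-3)
  expect_identical(ev$direction, oracle$direction)
})

test_that("samples exactly on the threshold follow the tie rule", {
  tr <- tibble::tibble(time = (0:4) * 0.2, si = c(2, 1, 0, -1, -2))
  ev <- reference_crossings(tr, 0)
  expect_equal(ev$time, 0.4)       # assigned to the sample on the threshold
  expect_identical(ev$direction, "on")
})

test_that("the ideal signal leads each crossing by the latency and round-trips", {
  cfg <- gating_config(threshold = 10, latency = 0.5)
  ev <- tibble::tibble(time = c(10, 12.3, 14.1),
                       direction = c("on", "off", "on"))
  sig <- ideal_gating(ev, cfg, span = c(0, 20))
  expect_equal(sig$time, ev$time - 0.5)
  expect_identical(sig$state, c(1L, 0L, 1L))
  # shifting the signal forward by the latency recovers the crossing times
  expect_equal(sig$time + cfg$latency, ev$time)
  # empty event list: constant signal
  empty <- ideal_gating(ev[0, ], cfg, span = c(0, 20))
  expect_identical(nrow(empty), 0L)
  # transitions before the span start clip to the span start
  sig2 <- ideal_gating(tibble::tibble(time = 0.2, direction = "on"), cfg,
                       span = c(0, 20))
  expect_equal(sig2$time, 0)
})

test_that("oracle predictions reproduce the ideal gating signal transition for transition", {
  tr <- test_trace(duration = 120, seed = 11)
  th <- estimate_threshold(tr, 30)
  cfg <- gating_config(th)
  span <- range(tr$time)
  ideal <- ideal_gating(reference_crossings(tr, th), cfg, span)
  sig <- generate_gating(oracle_stream(make_windows(tr, m = 15, J = 3), 3),
                         cfg, span)
  ge <- gating_errors(sig, ideal, pairing_window = 2, span = c(30, 120))
  expect_identical(attr(ge, "n_unmatched_pred"), 0L)
  expect_lt(max(ge$error_ms), 1e-6)
})

test_that("a crossing seen by two consecutive windows emits exactly one toggle", {
  cfg <- gating_config(threshold = 5, horizon_j = 3)
  # window 1 extrapolates the crossing just beyond its horizon (pre-trigger);
  # window 2 brackets the same crossing
  stream <- tibble::tibble(time = c(1.0, 1.2),
                           y_prev = c(6.2, 5.3),
                           y_last = c(5.3, 4.4))
  sig <- generate_gating(stream, cfg, span = c(0, 4))
  expect_identical(nrow(sig), 1L)
  ev <- gating_events(sig)
  expect_identical(nrow(ev), 1L)
  # the bracketed estimate refined the pre-trigger
  expect_identical(ev$condition, "bracketed")
  expect_equal(ev$detection_time, 1.0)
  expect_equal(ev$time, 1.8 + 0.2 * (5 - 4.4) / (4.4 - 5.3))
})

test_that("generated signals are time-ordered with alternating states", {
  set.seed(34)
  for (rep in 1:5) {
    tt <- (0:200) * 0.2
    stream <- tibble::tibble(time = tt,
                             y_prev = rnorm(201, 10, 4),
                             y_last = rnorm(201, 10, 4))
    sig <- generate_gating(stream, gating_config(threshold = 10),
                           span = c(0, 41))
    expect_true(all(diff(sig$time) > 0))
    if (nrow(sig) > 1)
      expect_true(all(diff(sig$state) != 0))
  }
})

test_that("flat (dummy) prediction streams never trigger and bad streams error", {
  tr <- test_trace(duration = 60, seed = 35)
  ws <- make_windows(tr, m = 15, J = 3)
  dummy <- fit_predictor(ws, "dummy", 3)
  stream <- predict_windows(dummy, ws)
  sig <- generate_gating(stream, gating_config(estimate_threshold(tr, 30)),
                         span = range(tr$time))
  expect_identical(nrow(sig), 0L)
  expect_error(generate_gating(stream[c(2, 1), ], gating_config(10)),
               class = "respgate_input_error")
})
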