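#' Run the full gating pipeline on one trace
#'
#' End-to-end execution of the online gating scheme: threshold estimation
#' from the burn-in segment, windowing, prediction (static, adaptive, Kalman,
#' persistence or oracle), crossing-time interpolation, latency-compensated
#' gating-signal generation, and amplitude/temporal metrics against the ideal
#' signal.
#'
#' Methods:
#' * `"adaptive"`: online linear regression with the burn-in period;
#'   refits continuously (set `refit_every = Inf` for a static fit on the
#'   burn-in data only). Evaluation starts right after the burn-in.
#' * `"ols"`, `"ridge"`, `"l2l1"`: static fit on the chronological training
#'   split (70% minus its validation block); evaluation on the test split.
#' * `"kalman"`: constant-velocity filter baseline on the test split.
#' * `"dummy"`: persistence predictions for the amplitude metrics; the beam
#'   toggles at the true crossing times (no prediction, no latency
#'   compensation).
#' * `"oracle"`: true future samples as predictions (best-case bound).
#'
#' @param trace Trace data frame (e.g. [simulate_trace()] or [read_trace()]).
#' @param channel Channel to gate on (default `"si"`).
#' @param method One of `"adaptive"`, `"ols"`, `"ridge"`, `"l2l1"`,
#'   `"kalman"`, `"dummy"`, `"oracle"`.
#' @param prediction_window Forecast span (s): 0.4 (under-prediction, j = 2)
#'   or 0.6 (over-prediction, j = 3) at 5 Hz.
#' @param m Input window length in samples.
#' @param burn_in Burn-in length (s) for the threshold and the adaptive fit.
#' @param refit_every Adaptive refit cadence in observed labels.
#' @param latency End-to-end system latency (s).
#' @param dt_max Pre-trigger margin (s).
#' @param beam_on_below Beam on below the threshold?
#' @param lambda_grid Optional penalty grid for ridge/l2l1.
#' @param kalman_q,kalman_r Kalman noise parameters.
#' @param pairing_window Event-pairing window (s); default half the mean
#'   breathing period estimated from the reference crossings.
#' @return A `gating_run`: list with `report` (one-row metrics tibble),
#'   `signal`, `ideal`, `reference`, `stream`, `threshold`, `config`,
#'   `eval_span`, `method` and the input `trace`.
#' @examples
#' \donttest{
#' tr <- simulate_trace(breathing_preset("liver", duration = 120, seed = 7))
#' run <- run_gating_pipeline(tr, method = "oracle")
#' glance(run)
#' }
#' @export
run_gating_pipeline <- function(trace, channel = "si",
                                method = c("adaptive", "ols", "ridge",
                                           "l2l1", "kalman", "dummy",
                                           "oracle"),
                                prediction_window = 0.6, m = 15L,
                                burn_in = 30, refit_every = 1,
                                latency = 0.5, dt_max = 0.1,
                                beam_on_below = TRUE, lambda_grid = NULL,
                                kalman_q = 10, kalman_r = 0.1,
                                pairing_window = NULL) {
  method <- match.arg(method)
  assert_trace(trace, channel)
  dt <- trace_dt(trace)
  j <- as.integer(round(prediction_window / dt))
  if (abs(j * dt - prediction_window) > 1e-9 || j < 2L)
    abort("`prediction_window` must be an integer multiple (>= 2) of the sampling period.",
          class = "respgate_parameter_error")
  n <- nrow(trace)
  if (n < round(burn_in / dt) + m + j)
    abort("trace shorter than burn_in + m + J samples.",
          class = "respgate_input_error")

  th <- estimate_threshold(trace, burn_in, channel)
  cfg <- gating_config(threshold = th, dt = dt, latency = latency,
                       horizon_j = j, dt_max = dt_max,
                       beam_on_below = beam_on_below)
  span <- range(trace$time)
  ref <- reference_crossings(trace, th, channel)
  ideal <- ideal_gating(ref, cfg, span)
  ws <- make_windows(trace, channel, m = m, J = j)

  stream <- switch(
    method,
    adaptive = adaptive_stream(trace, channel, m, j, burn_in, refit_every),
    oracle = oracle_stream(ws, j),
    dummy = predict_windows(fit_predictor(ws, "dummy", j), ws),
    kalman = {
      sp <- split_windows(ws)
      kalman_stream(trace, channel, j, start_time = sp$test$anchor_times[1L],
                    q = kalman_q, r = kalman_r)
    },
    {
      sp <- split_windows(ws)
      model <- fit_predictor(sp$train, method, j, lambda_grid = lambda_grid)
      predict_windows(model, sp$test)
    }
  )
  if (nrow(stream) == 0L)
    abort("no predictions emitted; trace too short for the burn-in.",
          class = "respgate_input_error")

  signal <- if (method == "dummy") crossing_time_gating(ref, cfg, span)
            else generate_gating(stream, cfg, span)

  eval_start <- if (method %in% c("oracle", "dummy"))
    max(burn_in + span[1L], stream$time[1L] + j * dt)
  else stream$time[1L] + j * dt
  eval_span <- c(eval_start, span[2L])

  # amplitude metrics at the j-step horizon over the evaluated stream
  idx <- match(stream$time, trace$time)
  ok <- !is.na(idx) & (idx + j) <= n & stream$time >= eval_start - j * dt
  y <- trace[[channel]][idx[ok] + j]
  yhat <- stream$y_last[ok]

  if (is.null(pairing_window)) {
    on_times <- ref$time[ref$direction == "on"]
    pairing_window <- if (length(on_times) > 1L)
      mean(diff(on_times)) / 2 else 2
  }
  in_span <- function(ev) ev[ev$time >= eval_span[1L] &
                               ev$time <= eval_span[2L], ]
  pred_events <- gating_events(signal)
  crossing <- crossing_errors(in_span(pred_events), in_span(ref),
                              pairing_window)
  gating <- gating_errors(signal, ideal, pairing_window, span = eval_span)
  accuracy <- gating_accuracy(signal, ideal, span = eval_span)
  report <- metrics_report(y, yhat, crossing, gating, accuracy,
                           total_time = diff(eval_span))

  structure(
    list(report = report, signal = signal, ideal = ideal, reference = ref,
         stream = stream, threshold = th, config = cfg,
         eval_span = eval_span, method = method, channel = channel,
         trace = trace),
    class = "gating_run"
  )
}

#' @export
print.gating_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<gating_run> %s (j = %d, Th = %.2f mm)\n",
           "  MAE %.3f mm | RMSE %.3f mm | R^2 %.4f\n",
           "  crossing %.0f +/- %.0f ms | gating %.0f +/- %.0f ms | ",
           "accuracy %.2f%% (%d events over %.0f s)\n"),
    x$method, x$config$horizon_j, x$threshold,
    r$mae, r$rmse, r$r2,
    r$crossing_error_mean, r$crossing_error_sd,
    r$gating_error_mean, r$gating_error_sd,
    r$gating_accuracy, r$n_events, r$total_time))
  invisible(x)
}

#' @export
glance.gating_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble(method = x$method, channel = x$channel,
           horizon_j = x$config$horizon_j, threshold = x$threshold),
    x$report
  )
}

#' @export
tidy.gating_run <- function(x, ...) {
  out <- as_tibble(x$signal)
  out$signal <- "predicted"
  ideal <- as_tibble(x$ideal)
  ideal$signal <- "ideal"
  bind_rows(out, ideal)
}

#' Simulate a cohort of synthetic patient traces
#'
#' Draws per-patient breathing characteristics (mean period, mean SI
#' excursion) from the reported cohort ranges — liver organs: period
#' 2.9-7.4 s, SI 5.6-40.1 mm; lung tumors: period 2.4-5.4 s, SI 3.1-25.2 mm —
#' using range-truncated normal draws centred on the cohort means, and
#' simulates one trace per patient. AP/LR amplitudes keep the cohort's
#' proportion to SI.
#'
#' @param preset `"liver"` or `"lung"`.
#' @param n Number of traces (patients).
#' @param duration Trace duration (s).
#' @param seed Cohort seed; per-trace seeds are derived from it.
#' @param dir Optional directory: traces are also written as CSV
#'   (`<preset>_<k>.csv`, schema `time,si,ap,lr,total`).
#' @param ... Further overrides passed to [breathing_preset()].
#' @return Named list of `resp_trace` tibbles; when `dir` is given, the file
#'   paths are attached as attribute `"files"`.
#' @export
simulate_cohort <- function(preset = c("liver", "lung"), n = 5L,
                            duration = 300, seed = NULL, dir = NULL, ...) {
  preset <- match.arg(preset)
  rng <- switch(preset,
    liver = list(period = c(2.9, 4.6, 7.4), amp = c(5.6, 21.3, 40.1)),
    lung = list(period = c(2.4, 3.4, 5.4), amp = c(3.1, 16.2, 25.2))
  )
  draws <- with_seed(seed, {
    list(
      period = rtrunc_range(n, rng$period),
      amp = rtrunc_range(n, rng$amp),
      seeds = sample.int(.Machine$integer.max - 1L, n)
    )
  })
  base <- breathing_preset(preset)
  traces <- lapply(seq_len(n), function(k) {
    scale_k <- draws$amp[k] / base$mean_amp_si
    simulate_trace(breathing_preset(
      preset,
      mean_period = draws$period[k],
      mean_amp_si = draws$amp[k],
      mean_amp_ap = base$mean_amp_ap * scale_k,
      mean_amp_lr = base$mean_amp_lr * scale_k,
      duration = duration,
      seed = draws$seeds[k],
      ...
    ))
  })
  names(traces) <- sprintf("%s_%02d", preset, seq_len(n))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- file.path(dir, paste0(names(traces), ".csv"))
    for (k in seq_len(n)) write_trace(traces[[k]], files[k])
    attr(traces, "files") <- files
  }
  traces
}

# truncated-normal draw over a (min, mean, max) range triple
rtrunc_range <- function(n, r) {
  out <- rnorm_trunc(n, r[2L], (r[3L] - r[1L]) / 4, lower = r[1L])
  pmin(out, r[3L])
}

#' Burn-in length sweep: adaptive vs static gating accuracy
#'
#' For each burn-in length, runs the gating pipeline on every trace of a
#' cohort twice — adaptive (continuous refit) and static (single fit on the
#' burn-in data, `refit_every = Inf`) — and summarises the gating accuracy.
#'
#' @param traces List of trace data frames (e.g. [simulate_cohort()]).
#' @param burn_ins Numeric vector of burn-in lengths (s).
#' @param ... Passed to [run_gating_pipeline()] (channel, prediction window,
#'   latency, ...).
#' @return Tibble with one row per `(burn_in, mode)`: `n`, `mean`, `q25`,
#'   `median`, `q75` of gating accuracy (%). Per-trace accuracies are
#'   attached as attribute `"per_trace"`. Burn-ins too long for a trace are
#'   skipped with a warning.
#' @export
sweep_burn_in <- function(traces, burn_ins, ...) {
  if (length(burn_ins) == 0L)
    abort("`burn_ins` must be non-empty.",
          class = "respgate_parameter_error")
  grid <- expand.grid(burn_in = burn_ins, mode = c("adaptive", "static"),
                      trace = seq_along(traces), stringsAsFactors = FALSE)
  rows <- map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tr <- traces[[g$trace]]
    acc <- tryCatch({
      run <- run_gating_pipeline(
        tr, method = "adaptive", burn_in = g$burn_in,
        refit_every = if (g$mode == "adaptive") 1 else Inf, ...)
      run$report$gating_accuracy
    }, respgate_input_error = function(e) {
      warn(sprintf("burn-in %g s skipped for trace %d: %s",
                   g$burn_in, g$trace, conditionMessage(e)))
      NA_real_
    })
    tibble(burn_in = g$burn_in, mode = g$mode, trace = g$trace,
           gating_accuracy = acc)
  })
  per_trace <- rows[!is.na(rows$gating_accuracy), ]
  out <- per_trace |>
    group_by(.data$burn_in, .data$mode) |>
    summarise(n = dplyr::n(),
              mean = mean(.data$gating_accuracy),
              q25 = unname(stats::quantile(.data$gating_accuracy, 0.25)),
              median = stats::median(.data$gating_accuracy),
              q75 = unname(stats::quantile(.data$gating_accuracy, 0.75)),
              .groups = "drop")
  attr(out, "per_trace") <- per_trace
  out
}

#' Compare two sets of per-trace gating runs
#'
#' Wilcoxon signed-rank comparison of a metric across paired runs (same
#' traces, two methods).
#'
#' @param runs_a,runs_b Lists of `gating_run` objects, paired by position.
#' @param metric Column of the metrics report to compare.
#' @return Two-sided p-value from [compare_models()].
#' @export
compare_runs <- function(runs_a, runs_b, metric = "gating_accuracy") {
  a <- map_dbl(runs_a, ~ .x$report[[metric]])
  b <- map_dbl(runs_b, ~ .x$report[[metric]])
  compare_models(a, b)
}
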