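#' Breathing-trace simulation parameters
#'
#' Bundles the parameters of the quasi-periodic breathing model used by
#' [simulate_trace()]. Superior-inferior (SI) motion follows, cycle by cycle,
#' a \eqn{\sin^{2n}} inhale-excursion profile (rest at exhale), with per-cycle
#' period and amplitude variability, linear baseline drift and additive
#' Gaussian measurement noise. Anterior-posterior (AP) and left-right (LR)
#' motion are scaled, phase-lagged copies of the clean SI waveform with their
#' own noise.
#'
#' Defaults emulate the liver cohort of the motivating clinical setting
#' (mean SI excursion 21.3 mm, mean cycle 4.6 s, 5 Hz sampling).
#'
#' @param mean_period Mean breathing period (s).
#' @param period_sd Per-cycle standard deviation of the period (s). Drawn
#'   periods are truncated below at `0.5 * mean_period`.
#' @param mean_amp_si,mean_amp_ap,mean_amp_lr Mean peak-to-trough excursion
#'   per axis (mm). AP/LR waveforms are scaled SI copies with ratios
#'   `mean_amp_ap / mean_amp_si` and `mean_amp_lr / mean_amp_si`.
#' @param amp_sd_frac Per-cycle amplitude standard deviation as a fraction of
#'   the mean amplitude (dimensionless). Drawn amplitudes are truncated at 0.
#' @param drift_mm_per_min Linear baseline drift of the SI channel (mm/min).
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to each
#'   sampled channel (mm).
#' @param shape_exponent Even integer `2n` of the \eqn{\sin^{2n}} cycle
#'   profile; larger values lengthen the exhale plateau.
#' @param ap_lag,lr_lag Phase lag of the AP/LR waveforms relative to SI (s).
#' @param duration Trace duration (s).
#' @param sample_period Sampling period \eqn{\Delta T} (s); default 0.2
#'   (5 Hz imaging).
#' @param seed Integer seed; fixed seed gives a bit-identical trace.
#'
#' @return A `breathing_params` list.
#' @seealso [simulate_trace()], [breathing_preset()]
#' @export
breathing_params <- function(mean_period = 4.6,
                             period_sd = 0.4,
                             mean_amp_si = 21.3,
                             mean_amp_ap = 7.9,
                             mean_amp_lr = 9.3,
                             amp_sd_frac = 0.1,
                             drift_mm_per_min = 0.5,
                             noise_sd = 0.3,
                             shape_exponent = 4,
                             ap_lag = 0.1,
                             lr_lag = 0.05,
                             duration = 300,
                             sample_period = 0.2,
                             seed = NULL) {
  stopifnot_scalar_num(mean_period, "mean_period", 0, strict = TRUE)
  stopifnot_scalar_num(period_sd, "period_sd", 0)
  stopifnot_scalar_num(mean_amp_si, "mean_amp_si", 0)
  stopifnot_scalar_num(mean_amp_ap, "mean_amp_ap", 0)
  stopifnot_scalar_num(mean_amp_lr, "mean_amp_lr", 0)
  stopifnot_scalar_num(amp_sd_frac, "amp_sd_frac", 0)
  stopifnot_scalar_num(noise_sd, "noise_sd", 0)
  stopifnot_scalar_num(duration, "duration", 0, strict = TRUE)
  stopifnot_scalar_num(sample_period, "sample_period", 0, strict = TRUE)
  if (!is.numeric(shape_exponent) || length(shape_exponent) != 1L ||
      shape_exponent < 2 || shape_exponent %% 2 != 0)
    abort("`shape_exponent` must be a positive even integer.",
          class = "respgate_parameter_error")
  structure(
    list(mean_period = mean_period, period_sd = period_sd,
         mean_amp_si = mean_amp_si, mean_amp_ap = mean_amp_ap,
         mean_amp_lr = mean_amp_lr, amp_sd_frac = amp_sd_frac,
         drift_mm_per_min = drift_mm_per_min, noise_sd = noise_sd,
         shape_exponent = shape_exponent, ap_lag = ap_lag, lr_lag = lr_lag,
         duration = duration, sample_period = sample_period, seed = seed),
    class = "breathing_params"
  )
}

#' Cohort presets for the breathing simulator
#'
#' Parameter presets matching the reported motion statistics of liver organs
#' (mean SI excursion 21.3 mm, mean cycle 4.6 s) and lung tumors (16.2 mm,
#' 3.4 s) tracked on 2D cine-MR at 5 Hz.
#'
#' @param preset `"liver"` or `"lung"`.
#' @param ... Overrides passed to [breathing_params()].
#' @return A `breathing_params` list.
#' @export
breathing_preset <- function(preset = c("liver", "lung"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    liver = list(mean_period = 4.6, mean_amp_si = 21.3,
                 mean_amp_ap = 7.9, mean_amp_lr = 9.3),
    lung = list(mean_period = 3.4, mean_amp_si = 16.2,
                mean_amp_ap = 4.2, mean_amp_lr = 2.8)
  )
  do.call(breathing_params, utils::modifyList(base, list(...)))
}

# rejection-sampled truncated normal; deterministic under a seeded RNG
rnorm_trunc <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  for (iter in seq_len(100L)) {
    bad <- out <= lower
    if (!any(bad)) break
    out[bad] <- rnorm(sum(bad), mean, sd)
  }
  pmax(out, lower + 1e-9)
}

#' Simulate a synthetic respiratory trace
#'
#' Generates a quasi-periodic multi-axis respiratory trajectory sampled at a
#' fixed period. Each cycle draws its own period and SI excursion; within a
#' cycle the SI position follows `b * sin(pi * u)^(2n)` for cycle phase
#' `u` in `[0, 1)`, so the trace rests near its exhale baseline (value 0
#' before drift/noise) and rises to `b` at peak inhale. Cycle boundaries fall
#' at the exhale plateau, which keeps the waveform continuous and smooth when
#' the amplitude changes between cycles.
#'
#' @param params A [breathing_params()] object.
#' @return A `resp_trace` tibble with columns `time` (s), `si`, `ap`, `lr`
#'   and `total` (mm). `total` is the 3D total motion, the per-sample
#'   Euclidean displacement from the per-axis series mean (see
#'   [total_motion()]). Attributes: `dt` (sampling period) and `label`.
#' @examples
#' tr <- simulate_trace(breathing_preset("liver", duration = 60, seed = 1))
#' head(tr)
#' @export
simulate_trace <- function(params) {
  if (!inherits(params, "breathing_params"))
    abort("`params` must be created by breathing_params().",
          class = "respgate_parameter_error")
  p <- params
  with_seed(p$seed, {
    # draw enough cycles to cover the duration plus the largest phase lag
    horizon <- p$duration + max(p$ap_lag, p$lr_lag, 0) + 2 * p$mean_period
    n_cycles <- ceiling(horizon / max(p$mean_period - 3 * p$period_sd,
                                      0.5 * p$mean_period)) + 2L
    periods <- rnorm_trunc(n_cycles, p$mean_period, p$period_sd,
                           lower = 0.5 * p$mean_period)
    amps <- rnorm_trunc(n_cycles, p$mean_amp_si,
                        p$amp_sd_frac * p$mean_amp_si, lower = 0)
    starts <- cumsum(c(0, periods))

    clean_si <- function(t) {
      k <- findInterval(t, starts)
      u <- (t - starts[k]) / periods[k]
      amps[k] * sin(pi * u)^p$shape_exponent
    }

    times <- seq(0, p$duration, by = p$sample_period)
    n <- length(times)
    drift <- p$drift_mm_per_min * times / 60
    si <- clean_si(times) + drift + rnorm(n, 0, p$noise_sd)
    ratio_ap <- if (p$mean_amp_si > 0) p$mean_amp_ap / p$mean_amp_si else 0
    ratio_lr <- if (p$mean_amp_si > 0) p$mean_amp_lr / p$mean_amp_si else 0
    ap <- ratio_ap * clean_si(times + p$ap_lag) + rnorm(n, 0, p$noise_sd)
    lr <- ratio_lr * clean_si(times + p$lr_lag) + rnorm(n, 0, p$noise_sd)
    new_resp_trace(times, si, ap, lr, dt = p$sample_period,
                   label = "synthetic")
  })
}

new_resp_trace <- function(time, si, ap, lr, dt, label = "synthetic",
                           total = NULL) {
  if (is.null(total)) total <- total_motion(si, ap, lr)
  out <- tibble(time = time, si = si, ap = ap, lr = lr, total = total)
  attr(out, "dt") <- dt
  attr(out, "label") <- label
  class(out) <- c("resp_trace", class(out))
  out
}

#' Combine per-axis motion into the 3D total motion
#'
#' Per-sample Euclidean norm of the (SI, AP, LR) displacement from a reference
#' position, the single-amplitude summary used for amplitude-based gating.
#'
#' @param si,ap,lr Equal-length numeric series (mm).
#' @param reference `"series_mean"` (default; displacement from each axis's
#'   mean), `"first_sample"`, or a numeric length-3 vector of reference
#'   positions `(si, ap, lr)`.
#' @return Numeric series of non-negative displacements (mm).
#' @examples
#' total_motion(3, 4, 0, reference = c(0, 0, 0))  # 3-4-5 triangle
#' @export
total_motion <- function(si, ap, lr, reference = "series_mean") {
  if (length(ap) != length(si) || length(lr) != length(si))
    abort("`si`, `ap` and `lr` must have equal length.",
          class = "respgate_input_error")
  ref <- if (is.numeric(reference)) {
    if (length(reference) != 3L)
      abort("numeric `reference` must have length 3.",
            class = "respgate_input_error")
    reference
  } else {
    switch(match.arg(reference, c("series_mean", "first_sample")),
           series_mean = c(mean(si), mean(ap), mean(lr)),
           first_sample = c(si[1L], ap[1L], lr[1L]))
  }
  sqrt((si - ref[1L])^2 + (ap - ref[2L])^2 + (lr - ref[3L])^2)
}

#' @export
print.resp_trace <- function(x, ...) {
  cat(sprintf("<resp_trace> %s: %d samples, %.1f s at dt = %g s\n",
              attr(x, "label") %||% "trace", nrow(x),
              max(x$time) - min(x$time), trace_dt(x)))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sampling period of a trace, from the attribute or the time column
trace_dt <- function(trace) {
  dt <- attr(trace, "dt")
  if (!is.null(dt)) return(dt)
  stats::median(diff(trace$time))
}

assert_trace <- function(trace, channel = NULL) {
  if (!is.data.frame(trace) || !"time" %in% names(trace))
    abort("`trace` must be a data frame with a `time` column.",
          class = "respgate_input_error")
  if (nrow(trace) < 2L)
    abort("`trace` must have at least 2 samples.",
          class = "respgate_input_error")
  if (is.unsorted(trace$time, strictly = TRUE))
    abort("`trace$time` must be strictly increasing.",
          class = "respgate_input_error")
  if (!is.null(channel) && !channel %in% names(trace))
    abort(sprintf("channel `%s` not found in trace.", channel),
          class = "respgate_input_error")
  invisible(trace)
}
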