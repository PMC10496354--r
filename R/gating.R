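#' Gating controller configuration
#'
#' @param threshold Gating threshold `Th` (mm); typically from
#'   [estimate_threshold()].
#' @param dt Sampling period (s).
#' @param latency End-to-end system latency (s): imaging + target tracking +
#'   beam triggering. The ideal gating signal leads each true threshold
#'   crossing by exactly this much.
#' @param horizon_j Horizon index `j`; `j * dt` must be 0.4 s
#'   (under-prediction) or 0.6 s (over-prediction) at the defaults.
#' @param dt_max Pre-trigger margin (s): a crossing extrapolated at most this
#'   far beyond the prediction horizon still triggers (condition B), and a
#'   scheduled transition may lead its triggering decision by at most this
#'   much (the processing share of the latency budget).
#' @param beam_on_below If `TRUE` (default) the beam is on while the trace is
#'   below the threshold (gating during the exhale rest).
#' @param refractory Dead time (s) within which a second detection of a
#'   crossing in the same direction is merged with the first (default =
#'   latency).
#' @return A `gating_config` list.
#' @export
gating_config <- function(threshold, dt = 0.2, latency = 0.5, horizon_j = 3L,
                          dt_max = 0.1, beam_on_below = TRUE,
                          refractory = latency) {
  stopifnot_scalar_num(threshold, "threshold")
  stopifnot_scalar_num(dt, "dt", 0, strict = TRUE)
  stopifnot_scalar_num(latency, "latency", 0, strict = TRUE)
  stopifnot_scalar_num(dt_max, "dt_max", 0, strict = TRUE)
  if (dt_max > dt)
    abort("`dt_max` must satisfy 0 < dt_max <= dt.",
          class = "respgate_parameter_error")
  horizon_j <- as.integer(horizon_j)
  if (horizon_j < 2L)
    abort("`horizon_j` must be at least 2.",
          class = "respgate_parameter_error")
  structure(
    list(threshold = threshold, dt = dt, latency = latency,
         horizon_j = horizon_j, dt_max = dt_max,
         beam_on_below = isTRUE(beam_on_below), refractory = refractory),
    class = "gating_config"
  )
}

#' Patient-specific gating threshold from the burn-in segment
#'
#' The threshold is the mean of the chosen channel over the burn-in window
#' `[0, burn_in)` (times are taken relative to the trace start).
#'
#' @param trace Trace data frame.
#' @param burn_in Burn-in length (s).
#' @param channel Channel the threshold applies to (default `"si"`).
#' @return Threshold (mm).
#' @export
estimate_threshold <- function(trace, burn_in = 30, channel = "si") {
  assert_trace(trace, channel)
  rel <- trace$time - trace$time[1L]
  keep <- rel < burn_in
  if (!any(keep))
    abort("burn-in window contains no samples.",
          class = "respgate_input_error")
  mean(trace[[channel]][keep])
}

# crossing time of the segment through (t1 - dt, y0) -> (t1, y1) with
# threshold th, written in the over-the-horizon interpolation form so that
# predicted and reference crossings are numerically identical
interp_crossing <- function(t1, y0, y1, th, dt) {
  (th - y1) / (y1 - y0) * dt + t1
}

#' Predicted threshold-crossing time by linear interpolation
#'
#' Interpolates the two-horizon prediction pair linearly:
#' `T_cross = (Th - y_j) / (y_j - y_(j-1)) * dt + T_i + j * dt`.
#' A crossing is reported when the threshold is bracketed by the pair
#' (condition A) or when the extrapolated crossing falls at most `dt_max`
#' beyond the horizon `T_i + j * dt` (condition B, the pre-trigger). If the
#' pair is flat and equal to the threshold, the earlier horizon time is
#' returned (tie rule); a flat pair away from the threshold has no crossing.
#'
#' @param y_prev,y_last Predictions (mm) at horizons `j - 1` and `j`.
#' @param threshold Gating threshold `Th` (mm).
#' @param t_i Anchor time `T_i` of the prediction window (s).
#' @param horizon_j Horizon index `j`.
#' @param dt Sampling period (s).
#' @param dt_max Condition-B margin (s).
#' @return Crossing time (s) with attribute `condition` (`"bracketed"` or
#'   `"extrapolated"`), or `NA` when there is no admissible crossing.
#' @export
predicted_crossing_time <- function(y_prev, y_last, threshold, t_i,
                                    horizon_j = 3L, dt = 0.2, dt_max = 0.1) {
  t0 <- t_i + (horizon_j - 1L) * dt
  t1 <- t_i + horizon_j * dt
  if (y_prev == y_last) {
    if (threshold == y_prev)
      return(structure(t0, condition = "bracketed"))
    return(NA_real_)
  }
  tc <- interp_crossing(t1, y_prev, y_last, threshold, dt)
  if ((y_prev - threshold) * (y_last - threshold) <= 0)
    return(structure(tc, condition = "bracketed"))
  if (tc > t1 && tc <= t1 + dt_max)
    return(structure(tc, condition = "extrapolated"))
  NA_real_
}

#' Reference (gold-standard) threshold crossings of a trace
#'
#' Scans consecutive sample pairs of the chosen channel and emits
#' linearly-interpolated crossing times. `"on"` marks a crossing below the
#' threshold (beam activates when gating on low amplitudes), `"off"` a
#' crossing above. A sample landing exactly on the threshold is assigned to
#' that sample's time, with the direction taken from the following movement.
#'
#' @param trace Trace data frame.
#' @param threshold Gating threshold (mm).
#' @param channel Channel name.
#' @return Tibble of crossing events: `time` (s), `direction`
#'   (`"on"`/`"off"`).
#' @export
reference_crossings <- function(trace, threshold, channel = "si") {
  assert_trace(trace, channel)
  y <- trace[[channel]]
  t <- trace$time
  dt <- trace_dt(trace)
  s <- y - threshold
  n <- length(y)
  k <- seq_len(n - 1L)
  strict <- which(s[k] * s[k + 1L] < 0)
  touch <- which(s[k] == 0 & s[k + 1L] != 0)
  times <- c(interp_crossing(t[strict + 1L], y[strict], y[strict + 1L],
                             threshold, dt),
             t[touch])
  dirs <- c(ifelse(s[strict + 1L] < 0, "on", "off"),
            ifelse(s[touch + 1L] < 0, "on", "off"))
  ord <- order(times)
  tibble(time = times[ord], direction = dirs[ord])
}

# ---- gating signal container ---------------------------------------------

new_gating_signal <- function(time, state, span, initial_state = 0L,
                              events = NULL) {
  out <- tibble(time = time, state = as.integer(state))
  attr(out, "span") <- span
  attr(out, "initial_state") <- as.integer(initial_state)
  attr(out, "events") <- events
  class(out) <- c("gating_signal", class(out))
  out
}

#' @export
print.gating_signal <- function(x, ...) {
  sp <- attr(x, "span")
  cat(sprintf(
    "<gating_signal> %d transitions over [%.1f, %.1f] s (initial state %d)\n",
    nrow(x), sp[1L], sp[2L], attr(x, "initial_state")))
  NextMethod()
}

#' Crossing events recorded by a gating signal
#' @param signal A `gating_signal`.
#' @return Tibble of the signal's crossing events (`time`, `direction`, and
#'   for generated signals `detection_time` and `condition`), or `NULL` for
#'   signals built without event provenance.
#' @export
gating_events <- function(signal) attr(signal, "events")

#' Beam state of a gating signal at given times
#' @param signal A `gating_signal`.
#' @param t Numeric vector of query times (s).
#' @return Integer vector of 0/1 states.
#' @export
signal_state_at <- function(signal, t) {
  idx <- findInterval(t, signal$time)
  c(attr(signal, "initial_state"), signal$state)[idx + 1L]
}

# turn alternating candidate transitions into a valid signal: sort by time,
# keep only actual state changes given the initial state
sweep_transitions <- function(time, state, span, initial_state, events) {
  ord <- order(time)
  time <- time[ord]; state <- state[ord]
  if (!is.null(events)) events <- events[ord, , drop = FALSE]
  cur <- initial_state
  keep <- logical(length(time))
  for (i in seq_along(time)) {
    if (state[i] != cur) {
      keep[i] <- TRUE
      cur <- state[i]
    }
  }
  new_gating_signal(time[keep], state[keep], span, initial_state,
                    events = if (is.null(events)) NULL
                             else as_tibble(events[keep, , drop = FALSE]))
}

event_state <- function(direction, beam_on_below) {
  on_state <- if (beam_on_below) 1L else 0L
  ifelse(direction == "on", on_state, 1L - on_state)
}

#' Ideal gating signal from reference crossings
#'
#' The ideal beam signal leads every true threshold crossing by exactly the
#' system latency, so that the beam state change coincides with the crossing.
#' The state before the first transition is the complement of the first
#' transition's state. Transitions scheduled before the span start are
#' clipped to the span start.
#'
#' @param events Crossing-event tibble from [reference_crossings()].
#' @param cfg A [gating_config()].
#' @param span Length-2 numeric `(start, end)` of the signal's domain (s).
#' @return A `gating_signal`: tibble of `(time, state)` transitions with
#'   attributes `span`, `initial_state` and `events`.
#' @export
ideal_gating <- function(events, cfg, span) {
  shifted_gating(events, cfg, span, lead = cfg$latency)
}

#' No-prediction controller: toggle at the true crossing times
#'
#' The "dummy" controller of the gating scheme: it reacts exactly when the
#' trace crosses the threshold, with no motion prediction and hence no
#' latency compensation. Each of its transitions therefore lags the ideal
#' signal by exactly the system latency.
#'
#' @inheritParams ideal_gating
#' @return A `gating_signal`.
#' @export
crossing_time_gating <- function(events, cfg, span) {
  shifted_gating(events, cfg, span, lead = 0)
}

shifted_gating <- function(events, cfg, span, lead) {
  if (!inherits(cfg, "gating_config"))
    abort("`cfg` must be a gating_config.", class = "respgate_input_error")
  if (is.null(events) || nrow(events) == 0L)
    return(new_gating_signal(numeric(0), integer(0), span, 0L,
                             events = events))
  state <- event_state(events$direction, cfg$beam_on_below)
  times <- pmax(events$time - lead, span[1L])
  sweep_transitions(times, state, span,
                    initial_state = 1L - state[1L], events = events)
}

#' Generate the latency-compensated gating signal from a prediction stream
#'
#' Implements the online trigger logic. At each anchor time the two-horizon
#' prediction pair is interpolated for a threshold crossing
#' ([predicted_crossing_time()]): a bracketed crossing (condition A) or an
#' extrapolated crossing at most `dt_max` beyond the horizon (condition B,
#' pre-trigger) schedules a beam toggle at `crossing - latency`. The toggle
#' direction follows the predicted slope (descending = beam on when
#' `beam_on_below`); a flat pair never triggers. A second detection of the
#' same crossing (same direction, crossing estimates within `refractory`)
#' does not emit a new toggle: if the pending toggle came from a pre-trigger
#' and the new detection brackets the crossing, the more accurate bracketed
#' estimate replaces the extrapolated one, otherwise the detection is
#' ignored. Scheduled toggles are floored at `dt_max` before the decision
#' that produced the event's final crossing estimate (causality: a command
#' formed once the frame at `T_i` has been processed can realise a transition
#' at most the processing margin before `T_i` on the image-timestamp axis).
#' With the default geometry (`latency = j * dt - dt_max` for `j = 3`) this
#' floor never binds for over-prediction, while for under-prediction
#' (`j = 2`) it binds on most events — gating errors then exceed crossing
#' errors, the structural cost of a horizon shorter than the latency.
#'
#' The state before the first transition is inferred from the first detected
#' crossing (equivalently, from which side of the threshold the trace starts
#' on). Pass `initial_state` to force it.
#'
#' @param stream Tibble with columns `time` (anchor times `T_i`, strictly
#'   increasing), `y_prev`, `y_last` (the two-horizon predictions, mm).
#' @param cfg A [gating_config()].
#' @param span Length-2 numeric signal domain; default covers the stream and
#'   its prediction horizon.
#' @param initial_state Optional forced 0/1 beam state at the span start.
#' @return A `gating_signal` whose `events` attribute records each detected
#'   crossing (`time`, `direction`, `detection_time`, `condition`).
#' @export
generate_gating <- function(stream, cfg, span = NULL, initial_state = NULL) {
  if (!inherits(cfg, "gating_config"))
    abort("`cfg` must be a gating_config.", class = "respgate_input_error")
  if (!is.data.frame(stream) ||
      !all(c("time", "y_prev", "y_last") %in% names(stream)))
    abort("`stream` needs columns time, y_prev, y_last.",
          class = "respgate_input_error")
  if (nrow(stream) > 1L && is.unsorted(stream$time, strictly = TRUE))
    abort("`stream$time` must be strictly increasing.",
          class = "respgate_input_error")
  if (is.null(span))
    span <- c(stream$time[1L],
              stream$time[nrow(stream)] + cfg$horizon_j * cfg$dt)

  j <- cfg$horizon_j; dt <- cfg$dt; th <- cfg$threshold
  t1 <- stream$time + j * dt
  yp <- stream$y_prev; yl <- stream$y_last
  denom <- yl - yp
  tc <- ifelse(denom == 0, NA_real_,
               interp_crossing(t1, yp, yl, th, dt))
  bracketed <- denom != 0 & (yp - th) * (yl - th) <= 0
  extrap <- denom != 0 & !bracketed & tc > t1 & tc <= t1 + cfg$dt_max
  cand <- which(bracketed | extrap)

  ev_time <- ev_det <- ev_floor <- numeric(0)
  ev_dir <- ev_cond <- character(0)
  for (i in cand) {
    dir <- if (yl[i] < yp[i]) "on" else "off"
    cond <- if (bracketed[i]) "bracketed" else "extrapolated"
    prev <- which(ev_dir == dir)
    prev <- if (length(prev)) prev[length(prev)] else 0L
    if (prev > 0L && abs(tc[i] - ev_time[prev]) <= cfg$refractory) {
      # same crossing seen again: a bracketing estimate refines a pending
      # pre-trigger; anything else is a duplicate. The causality floor moves
      # with the refining decision.
      if (ev_cond[prev] == "extrapolated" && cond == "bracketed") {
        ev_time[prev] <- tc[i]
        ev_cond[prev] <- cond
        ev_floor[prev] <- stream$time[i]
      }
    } else {
      ev_time <- c(ev_time, tc[i])
      ev_det <- c(ev_det, stream$time[i])
      ev_floor <- c(ev_floor, stream$time[i])
      ev_dir <- c(ev_dir, dir)
      ev_cond <- c(ev_cond, cond)
    }
  }
  events <- tibble(time = ev_time, direction = ev_dir,
                   detection_time = ev_det, condition = ev_cond)
  if (nrow(events) == 0L)
    return(new_gating_signal(numeric(0), integer(0), span,
                             initial_state %||% 0L, events = events))
  state <- event_state(events$direction, cfg$beam_on_below)
  times <- pmax(events$time - cfg$latency, ev_floor - cfg$dt_max)
  times <- pmax(times, span[1L])
  init <- initial_state %||% (1L - state[1L])
  sweep_transitions(times, state, span, initial_state = init,
                    events = events)
}
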