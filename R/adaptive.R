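#' Streaming state for the adaptive linear predictor
#'
#' The adaptive predictor trains on a short burn-in segment (30 s = 150
#' samples at 5 Hz by default) and then keeps refitting on an ever-growing
#' buffer while it predicts. A training pair enters the buffer only once its
#' label has actually been observed: the pair for the horizon-`k` coefficient
#' vector becomes available `k` samples after its window anchor, so the model
#' never sees the future it is asked to predict.
#'
#' @param m Input window length in samples.
#' @param horizon_j Horizon index `j` (2 or 3).
#' @param dt Sampling period (s).
#' @param burn_in_samples Samples before the first fit and first emitted
#'   prediction (default 150 = 30 s at 5 Hz).
#' @param refit_every Refit after this many newly observed labels
#'   (default 1 = every sample; `Inf` disables adaptation after the burn-in
#'   fit, reducing to the static model).
#' @return An `adaptive_state` to be advanced with [adaptive_step()].
#' @export
adaptive_state <- function(m = 15L, horizon_j = 3L, dt = 0.2,
                           burn_in_samples = 150L, refit_every = 1) {
  structure(
    list(samples = numeric(0), times = numeric(0),
         m = as.integer(m), horizon_j = as.integer(horizon_j), dt = dt,
         burn_in_samples = as.integer(burn_in_samples),
         refit_every = refit_every,
         model = NULL, fitted_pairs = 0L),
    class = "adaptive_state"
  )
}

# number of training pairs whose horizon-k label is observable after n samples
n_pairs_available <- function(n, m, k) max(0L, n - m - k + 1L)

#' Advance the adaptive predictor by one sample
#'
#' Appends the incoming sample, refits the model by full least squares on all
#' training pairs observed so far (when due), and — once past the burn-in —
#' emits the two-horizon prediction for the window ending at the new sample.
#'
#' @param state An [adaptive_state()].
#' @param new_sample Observed position (mm).
#' @param time Sample time (s); defaults to `(n - 1) * dt`.
#' @return List with `state` (updated) and `prediction` (`NULL` before the
#'   burn-in ends, else a one-row tibble `time`, `y_prev`, `y_last`).
#' @export
adaptive_step <- function(state, new_sample, time = NULL) {
  if (!inherits(state, "adaptive_state"))
    abort("`state` must be an adaptive_state.",
          class = "respgate_input_error")
  n <- length(state$samples) + 1L
  if (is.null(time)) time <- (n - 1L) * state$dt
  state$samples[n] <- new_sample
  state$times[n] <- time
  j <- state$horizon_j
  m <- state$m
  n_last <- n_pairs_available(n, m, j)
  due <- is.null(state$model) ||
    (n_last - state$fitted_pairs >= state$refit_every)
  if (n >= state$burn_in_samples && n_last >= 1L && due) {
    state$model <- refit_adaptive(state$samples, m, j, state$dt)
    state$fitted_pairs <- n_last
  }
  prediction <- NULL
  if (n > state$burn_in_samples && !is.null(state$model) && n >= m) {
    x <- state$samples[(n - m + 1L):n]
    yh <- predict_pair(state$model, x)
    prediction <- tibble(time = time, y_prev = yh[["prev"]],
                         y_last = yh[["last"]])
  }
  list(state = state, prediction = prediction)
}

# full OLS refit on all pairs observable from `samples`; per-horizon label
# availability: the horizon-k pair for anchor i exists once sample i+m-1+k
# has been seen
refit_adaptive <- function(samples, m, j, dt) {
  n <- length(samples)
  np <- n_pairs_available(n, m, j - 1L)
  nl <- n_pairs_available(n, m, j)
  Xp <- matrix(samples[outer(0:(np - 1L), 1:m, `+`)], np, m)
  beta_prev <- fit_ols(Xp, samples[(0:(np - 1L)) + m + j - 1L])
  Xl <- Xp[seq_len(nl), , drop = FALSE]
  beta_last <- fit_ols(Xl, samples[(0:(nl - 1L)) + m + j])
  new_predictor_model(beta_prev, beta_last, j, 0, "adaptive",
                      m = m, dt = dt, n_train = nl)
}

#' Adaptive prediction stream over a whole trace
#'
#' Replays the trace through [adaptive_step()] sample by sample.
#'
#' @param trace Trace data frame.
#' @param channel Channel name.
#' @inheritParams adaptive_state
#' @param burn_in Burn-in length (s); converted to samples with the trace's
#'   sampling period.
#' @return Tibble `time`, `y_prev`, `y_last` of all emitted predictions, with
#'   the final fitted model as attribute `"model"`.
#' @export
adaptive_stream <- function(trace, channel = "si", m = 15L, horizon_j = 3L,
                            burn_in = 30, refit_every = 1) {
  assert_trace(trace, channel)
  dt <- trace_dt(trace)
  st <- adaptive_state(m = m, horizon_j = horizon_j, dt = dt,
                       burn_in_samples = round(burn_in / dt),
                       refit_every = refit_every)
  x <- trace[[channel]]
  n <- length(x)
  times <- trace$time
  out_t <- out_p <- out_l <- numeric(n)
  k <- 0L
  for (i in seq_len(n)) {
    res <- adaptive_step(st, x[i], times[i])
    st <- res$state
    if (!is.null(res$prediction)) {
      k <- k + 1L
      out_t[k] <- res$prediction$time
      out_p[k] <- res$prediction$y_prev
      out_l[k] <- res$prediction$y_last
    }
  }
  out <- tibble(time = out_t[seq_len(k)], y_prev = out_p[seq_len(k)],
                y_last = out_l[seq_len(k)])
  attr(out, "model") <- st$model
  out
}
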