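#' Build sliding-window forecasting pairs from a trace
#'
#' Segments a trace channel into supervised pairs: each row holds an input
#' window of `m` consecutive samples and, as labels, the next `J` samples
#' (prediction horizons `1..J` samples ahead of the window's last sample,
#' the anchor). Successive rows advance by one sample.
#'
#' @param trace A trace data frame (e.g. from [simulate_trace()]) with a
#'   `time` column and the requested channel.
#' @param channel Channel to forecast: `"si"`, `"ap"`, `"lr"` or `"total"`.
#' @param m Input window length in samples (default 15, about 3 s at 5 Hz).
#' @param J Maximum horizon in samples (default 3, i.e. 0.6 s at 5 Hz).
#' @return A `window_set`: list with `inputs` (N x m matrix), `labels`
#'   (N x J matrix), `anchor_times` (time of each window's last sample),
#'   `m`, `J`, `dt` and `channel`.
#' @examples
#' tr <- simulate_trace(breathing_preset("liver", duration = 30, seed = 1))
#' ws <- make_windows(tr)
#' dim(ws$inputs)
#' @export
make_windows <- function(trace, channel = "si", m = 15L, J = 3L) {
  assert_trace(trace, channel)
  m <- as.integer(m); J <- as.integer(J)
  if (m < 1L || J < 1L)
    abort("`m` and `J` must be positive integers.",
          class = "respgate_parameter_error")
  x <- trace[[channel]]
  n <- length(x)
  if (n < m + J)
    abort(sprintf("trace too short: %d samples, need at least m + J = %d.",
                  n, m + J),
          class = "respgate_input_error")
  N <- n - m - J + 1L
  inputs <- matrix(x[outer(0:(N - 1L), 1:m, `+`)], N, m)
  labels <- matrix(x[outer(0:(N - 1L), m + 1:J, `+`)], N, J)
  colnames(inputs) <- paste0("lag_", (m - 1L):0L)
  colnames(labels) <- paste0("h", 1:J)
  new_window_set(inputs, labels, anchor_times = trace$time[m:(m + N - 1L)],
                 m = m, J = J, dt = trace_dt(trace), channel = channel)
}

new_window_set <- function(inputs, labels, anchor_times, m, J, dt, channel) {
  structure(
    list(inputs = inputs, labels = labels, anchor_times = anchor_times,
         m = m, J = J, dt = dt, channel = channel),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf(
    "<window_set> %d windows (m = %d, J = %d, dt = %g s, channel = %s)\n",
    nrow(x$inputs), x$m, x$J, x$dt, x$channel))
  invisible(x)
}

#' Number of windows in a window set
#' @param x A `window_set`.
#' @return Integer count of rows.
#' @export
n_windows <- function(x) nrow(x$inputs)

#' @export
tidy.window_set <- function(x, ...) {
  out <- as_tibble(cbind(x$inputs, x$labels))
  out$anchor_time <- x$anchor_times
  out[, c("anchor_time", setdiff(names(out), "anchor_time"))]
}

subset_window_set <- function(ws, idx) {
  new_window_set(ws$inputs[idx, , drop = FALSE],
                 ws$labels[idx, , drop = FALSE],
                 ws$anchor_times[idx], ws$m, ws$J, ws$dt, ws$channel)
}

#' Chronological train/validation/test split of a window set
#'
#' Partitions windows chronologically: the first `train_frac` of rows form
#' the training pool and the remaining rows the test set; the most recent
#' `val_frac_of_train` of the training pool is held out as a validation
#' block. Splits are deterministic (no shuffling): labels are future samples,
#' so a random split would leak future information into training.
#'
#' Non-integer boundaries are floored for the test and validation sizes and
#' the remainder goes to training, so e.g. `N = 10` yields 6/1/3.
#'
#' @param ws A `window_set` from [make_windows()].
#' @param train_frac,test_frac Fractions of rows for the training pool and
#'   test set; must sum to 1 (defaults 0.70/0.30).
#' @param val_frac_of_train Fraction of the training pool held out as the
#'   validation block (default 0.20).
#' @return Named list of `window_set`s: `train`, `validation`, `test`.
#' @export
split_windows <- function(ws, train_frac = 0.7, test_frac = 0.3,
                          val_frac_of_train = 0.2) {
  if (!inherits(ws, "window_set"))
    abort("`ws` must be a window_set.", class = "respgate_input_error")
  if (train_frac <= 0 || train_frac >= 1 || test_frac <= 0 || test_frac >= 1)
    abort("fractions must lie in (0, 1).", class = "respgate_parameter_error")
  if (abs(train_frac + test_frac - 1) > 1e-8)
    abort("`train_frac` + `test_frac` must equal 1.",
          class = "respgate_parameter_error")
  if (val_frac_of_train < 0 || val_frac_of_train >= 1)
    abort("`val_frac_of_train` must lie in [0, 1).",
          class = "respgate_parameter_error")
  N <- n_windows(ws)
  if (N < 10L)
    abort("need at least 10 windows to split.",
          class = "respgate_input_error")
  n_test <- floor(N * test_frac)
  n_pool <- N - n_test
  n_val <- floor(n_pool * val_frac_of_train)
  n_train <- n_pool - n_val
  list(
    train = subset_window_set(ws, seq_len(n_train)),
    validation = subset_window_set(ws, n_train + seq_len(n_val)),
    test = subset_window_set(ws, n_pool + seq_len(n_test))
  )
}
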