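#' Amplitude accuracy metrics
#'
#' Mean absolute error, root-mean-square error and coefficient of
#' determination between observed and predicted motion amplitudes:
#' `MAE = mean(|y - yhat|)`, `RMSE = sqrt(mean((y - yhat)^2))`,
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`.
#'
#' @param y Observed values (mm).
#' @param yhat Predicted values (mm).
#' @return Scalar metric. `rsq()` returns `NA` with a warning when `y` has
#'   zero variance (undefined).
#' @examples
#' mae(c(0, 0), c(1, -1))   # 1
#' rmse(c(0, 0), c(1, -1))  # 1
#' @export
mae <- function(y, yhat) {
  check_paired(y, yhat)
  mean(abs(y - yhat))
}

#' @rdname mae
#' @export
rmse <- function(y, yhat) {
  check_paired(y, yhat)
  sqrt(mean((y - yhat)^2))
}

#' @rdname mae
#' @export
rsq <- function(y, yhat) {
  check_paired(y, yhat)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warn("R^2 undefined: observed values have zero variance.")
    return(NA_real_)
  }
  1 - sum((y - yhat)^2) / ss_tot
}

check_paired <- function(y, yhat) {
  if (length(y) == 0L || length(y) != length(yhat))
    abort("`y` and `yhat` must be non-empty vectors of equal length.",
          class = "respgate_input_error")
  invisible(TRUE)
}

# one-to-one, direction-constrained nearest matching of event times within
# `window`; pairs are accepted in order of increasing |time difference|
match_events <- function(pred_time, pred_dir, ref_time, ref_dir, window) {
  pairs <- list()
  for (d in unique(c(pred_dir, ref_dir))) {
    pi <- which(pred_dir == d)
    ri <- which(ref_dir == d)
    if (!length(pi) || !length(ri)) next
    dmat <- abs(outer(pred_time[pi], ref_time[ri], `-`))
    cand <- which(dmat <= window, arr.ind = TRUE)
    if (!nrow(cand)) next
    cand <- cand[order(dmat[cand]), , drop = FALSE]
    used_p <- logical(length(pi)); used_r <- logical(length(ri))
    for (k in seq_len(nrow(cand))) {
      a <- cand[k, 1L]; b <- cand[k, 2L]
      if (used_p[a] || used_r[b]) next
      used_p[a] <- TRUE; used_r[b] <- TRUE
      pairs[[length(pairs) + 1L]] <-
        tibble(pred_time = pred_time[pi[a]], ref_time = ref_time[ri[b]],
               direction = d)
    }
  }
  if (!length(pairs))
    return(tibble(pred_time = numeric(0), ref_time = numeric(0),
                  direction = character(0)))
  arrange(bind_rows(pairs), .data$ref_time)
}

#' Temporal crossing errors between predicted and reference crossings
#'
#' Pairs each predicted crossing event with the nearest reference event of
#' the same direction within `pairing_window`, one-to-one, and reports the
#' absolute time differences. Unpaired events (missed or spurious crossings)
#' do not enter the errors; their counts are carried as attributes.
#'
#' @param pred_events,ref_events Crossing-event tibbles (`time`,
#'   `direction`), e.g. from [gating_events()] and [reference_crossings()].
#' @param pairing_window Maximum pairing distance (s); choose about half the
#'   mean breathing period.
#' @return Tibble of matched pairs: `pred_time`, `ref_time`, `direction`,
#'   `error_ms` (absolute, milliseconds). Attributes `n_unmatched_pred`,
#'   `n_unmatched_ref`.
#' @export
crossing_errors <- function(pred_events, ref_events, pairing_window = 2) {
  out <- match_events(pred_events$time, pred_events$direction,
                      ref_events$time, ref_events$direction, pairing_window)
  out$error_ms <- abs(out$pred_time - out$ref_time) * 1000
  attr(out, "n_unmatched_pred") <- nrow(pred_events) - nrow(out)
  attr(out, "n_unmatched_ref") <- nrow(ref_events) - nrow(out)
  out
}

signal_as_events <- function(signal, beam_on_below = TRUE) {
  on_state <- if (beam_on_below) 1L else 0L
  tibble(time = signal$time,
         direction = ifelse(signal$state == on_state, "on", "off"))
}

#' Temporal gating errors between a generated and the ideal gating signal
#'
#' As [crossing_errors()], but on the beam-state transitions of two gating
#' signals: each transition of `pred_signal` is paired with the nearest
#' same-direction transition of `ideal_signal` within `pairing_window`.
#'
#' @param pred_signal,ideal_signal `gating_signal` objects.
#' @param pairing_window Maximum pairing distance (s).
#' @param span Optional `(start, end)`; only transitions inside are compared.
#' @return Tibble of matched pairs with `error_ms`; attributes
#'   `n_unmatched_pred`, `n_unmatched_ref`.
#' @export
gating_errors <- function(pred_signal, ideal_signal, pairing_window = 2,
                          span = NULL) {
  pe <- signal_as_events(pred_signal)
  ie <- signal_as_events(ideal_signal)
  if (!is.null(span)) {
    pe <- pe[pe$time >= span[1L] & pe$time <= span[2L], ]
    ie <- ie[ie$time >= span[1L] & ie$time <= span[2L], ]
  }
  out <- match_events(pe$time, pe$direction, ie$time, ie$direction,
                      pairing_window)
  out$error_ms <- abs(out$pred_time - out$ref_time) * 1000
  attr(out, "n_unmatched_pred") <- nrow(pe) - nrow(out)
  attr(out, "n_unmatched_ref") <- nrow(ie) - nrow(out)
  out
}

#' Gating accuracy: fraction of therapy time with agreeing beam states
#'
#' `100 * (1 - T_err / total)`, where `T_err` is the duration over which the
#' two signals disagree, computed exactly by a sweep over the merged
#' transition times (no discretization).
#'
#' @param pred_signal,ideal_signal `gating_signal` objects.
#' @param span Length-2 numeric evaluation interval (s); defaults to the
#'   ideal signal's span.
#' @return Percentage in `[0, 100]`.
#' @export
gating_accuracy <- function(pred_signal, ideal_signal, span = NULL) {
  span <- span %||% attr(ideal_signal, "span")
  if (is.null(span) || diff(span) <= 0)
    abort("`span` must have positive duration.",
          class = "respgate_input_error")
  breaks <- sort(unique(c(span,
                          pred_signal$time[pred_signal$time > span[1L] &
                                             pred_signal$time < span[2L]],
                          ideal_signal$time[ideal_signal$time > span[1L] &
                                              ideal_signal$time < span[2L]])))
  left <- breaks[-length(breaks)]
  width <- diff(breaks)
  s1 <- signal_state_at(pred_signal, left)
  s2 <- signal_state_at(ideal_signal, left)
  100 * (1 - sum(width[s1 != s2]) / diff(span))
}

#' Paired model comparison by Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on per-patient (per-trace) metric pairs.
#'
#' @param metric_a,metric_b Equal-length paired metric vectors, one entry per
#'   patient/trace; at least 5 pairs.
#' @return Two-sided p-value; `NA` with a warning when all pairwise
#'   differences are zero (degenerate).
#' @export
compare_models <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 5L)
    abort("need equal-length paired vectors with n >= 5.",
          class = "respgate_input_error")
  if (all(metric_a == metric_b)) {
    warn("all paired differences are zero; test degenerate.")
    return(NA_real_)
  }
  stats::wilcox.test(metric_a, metric_b, paired = TRUE,
                     alternative = "two.sided")$p.value
}

#' Assemble a one-row metrics report
#'
#' @param y,yhat Observed/predicted amplitudes for the amplitude metrics.
#' @param crossing Matched-pair tibble from [crossing_errors()].
#' @param gating Matched-pair tibble from [gating_errors()].
#' @param accuracy Gating accuracy (%).
#' @param total_time Evaluated duration (s).
#' @return One-row tibble: `mae`, `rmse`, `r2` (mm / dimensionless),
#'   `crossing_error_mean`, `crossing_error_sd`, `gating_error_mean`,
#'   `gating_error_sd` (ms), `gating_accuracy` (%), `n_events`, `total_time`.
#' @export
metrics_report <- function(y, yhat, crossing, gating, accuracy, total_time) {
  tibble(
    mae = mae(y, yhat),
    rmse = rmse(y, yhat),
    r2 = rsq(y, yhat),
    crossing_error_mean = mean(crossing$error_ms),
    crossing_error_sd = sd(crossing$error_ms),
    gating_error_mean = mean(gating$error_ms),
    gating_error_sd = sd(gating$error_ms),
    gating_accuracy = accuracy,
    n_events = nrow(gating),
    total_time = total_time
  )
}
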