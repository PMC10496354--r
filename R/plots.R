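#' Plot a respiratory trace
#'
#' @param object A `resp_trace`.
#' @param channels Channels to draw.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.resp_trace <- function(object, channels = c("si", "total"), ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              cols = dplyr::all_of(channels),
                              names_to = "channel", values_to = "mm")
  ggplot(long, aes(x = .data$time, y = .data$mm,
                   colour = .data$channel)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = "position (mm)",
         title = attr(object, "label")) +
    theme_minimal()
}

#' Plot a gating signal as a step function
#'
#' @param object A `gating_signal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gating_signal <- function(object, ...) {
  sp <- attr(object, "span")
  df <- tibble(time = c(sp[1L], object$time, sp[2L]),
               state = c(attr(object, "initial_state"), object$state,
                         if (nrow(object)) object$state[nrow(object)]
                         else attr(object, "initial_state")))
  ggplot(df, aes(x = .data$time, y = .data$state)) +
    geom_step(linewidth = 0.4) +
    scale_y_continuous(breaks = c(0, 1), limits = c(-0.05, 1.05)) +
    labs(x = "time (s)", y = "beam state") +
    theme_minimal()
}

#' Plot a gating run: trace, threshold and both gating signals
#'
#' @param object A `gating_run` from [run_gating_pipeline()].
#' @param window Optional length-2 time window (s) to zoom into.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gating_run <- function(object, window = NULL, ...) {
  tr <- as_tibble(object$trace)[, c("time", object$channel)]
  names(tr)[2L] <- "mm"
  sigs <- tidy(object)
  sp <- attr(object$signal, "span")
  amp <- diff(range(tr$mm))
  base <- min(tr$mm) - 0.35 * amp
  step_df <- function(s, label, offset) {
    sub <- sigs[sigs$signal == label, ]
    tibble(time = c(sp[1L], sub$time, sp[2L]),
           y = base + offset * amp * 0.15 +
             0.1 * amp * c(if (label == "ideal")
                             attr(object$ideal, "initial_state")
                           else attr(object$signal, "initial_state"),
                           sub$state,
                           if (nrow(sub)) sub$state[nrow(sub)] else 0L),
           signal = label)
  }
  steps <- bind_rows(step_df(object$signal, "predicted", 0),
                     step_df(object$ideal, "ideal", -1.2))
  p <- ggplot() +
    geom_line(data = tr, aes(x = .data$time, y = .data$mm),
              linewidth = 0.3, colour = "grey30") +
    geom_hline(yintercept = object$threshold, linetype = 2,
               colour = "firebrick") +
    geom_step(data = steps, aes(x = .data$time, y = .data$y,
                                colour = .data$signal),
              linewidth = 0.5) +
    labs(x = "time (s)", y = sprintf("%s (mm)", object$channel),
         colour = NULL,
         title = sprintf("%s gating (j = %d), accuracy %.2f%%",
                         object$method, object$config$horizon_j,
                         object$report$gating_accuracy)) +
    theme_minimal()
  if (!is.null(window)) p <- p + coord_cartesian(xlim = window)
  p
}

#' Plot a burn-in sweep summary
#'
#' Mean gating accuracy with interquartile ribbons, adaptive vs static, as a
#' function of the burn-in (training) length.
#'
#' @param sweep Tibble from [sweep_burn_in()].
#' @return A ggplot.
#' @export
plot_burnin_sweep <- function(sweep) {
  ggplot(sweep, aes(x = .data$burn_in, colour = .data$mode,
                    fill = .data$mode)) +
    geom_ribbon(aes(ymin = .data$q25, ymax = .data$q75),
                alpha = 0.15, colour = NA) +
    geom_line(aes(y = .data$mean)) +
    geom_point(aes(y = .data$mean), size = 1) +
    labs(x = "burn-in / training length (s)", y = "gating accuracy (%)",
         colour = NULL, fill = NULL) +
    theme_minimal()
}
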