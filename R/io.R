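#' Read and write respiratory traces as CSV
#'
#' The interchange schema is one row per sample with header
#' `time,si,ap,lr,total` ('.' decimal separator, seconds and millimetres).
#' `read_trace()` recomputes nothing: a `total` column is used as-is when
#' present and otherwise derived with [total_motion()].
#'
#' @param trace A trace data frame.
#' @param path CSV file path.
#' @param label Free-text label attached to the trace (e.g. `"liver"`).
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns a
#'   `resp_trace` tibble.
#' @export
write_trace <- function(trace, path) {
  assert_trace(trace)
  cols <- intersect(c("time", "si", "ap", "lr", "total"), names(trace))
  readr::write_csv(as.data.frame(trace)[, cols], path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, label = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time", "si", "ap", "lr")
  if (!all(need %in% names(df)))
    abort(sprintf("trace CSV must have columns %s.",
                  paste(need, collapse = ", ")),
          class = "respgate_input_error")
  new_resp_trace(df$time, df$si, df$ap, df$lr,
                 dt = stats::median(diff(df$time)),
                 label = label %||% sub("\\.csv$", "", basename(path)),
                 total = if ("total" %in% names(df)) df$total else NULL)
}

#' Write a gating signal as a transitions CSV
#'
#' Schema: header `time,state`, one row per beam-state transition.
#'
#' @param signal A `gating_signal`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_gating_signal <- function(signal, path) {
  readr::write_csv(as.data.frame(signal)[, c("time", "state")], path)
  invisible(path)
}

#' Load simulator presets from a YAML file
#'
#' The package ships cohort presets (`liver`, `lung`) in
#' `inst/extdata/presets.yaml`; a user file with the same structure (named
#' blocks of [breathing_params()] fields) can be supplied instead.
#'
#' @param preset Preset name.
#' @param path YAML file; defaults to the bundled presets.
#' @return A `breathing_params` object.
#' @export
read_preset_yaml <- function(preset,
                             path = system.file("extdata", "presets.yaml",
                                                package = "respgate")) {
  cfg <- yaml::read_yaml(path)
  if (!preset %in% names(cfg))
    abort(sprintf("preset `%s` not found in %s.", preset, path),
          class = "respgate_input_error")
  do.call(breathing_params, cfg[[preset]])
}

#' Read a pipeline run configuration from YAML
#'
#' Convenience loader for the command-line front-end: returns a named list of
#' [run_gating_pipeline()] arguments plus optional `input`/`preset` fields.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort(sprintf("config file not found: %s", path),
          class = "respgate_input_error")
  yaml::read_yaml(path)
}
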