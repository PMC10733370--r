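#' Read and write the package's tidy CSV formats
#'
#' Eye traces are stored as CSV with columns `time_s`, `position_deg`;
#' trial tables as `neuron_id`, `direction_deg`, `trial`, `time_s`, `F`;
#' spike lists as `unit_id`, `direction_deg`, `trial`, `spike_time_s`;
#' cell maps as `x_um`, `y_um`, `area`. Generative ground truth travels
#' in a JSON sidecar (`<file>.json`) so parameter-recovery scoring
#' survives a round trip through disk.
#'
#' @param trace,trials,map Objects produced by the generators.
#' @param path Output CSV path.
#' @param sidecar Write the ground-truth JSON sidecar (default TRUE).
#' @return `path`, invisibly (writers); the reconstructed object
#'   (readers).
#' @name okr_io
NULL

write_sidecar <- function(obj, path) {
  gt <- attr(obj, "ground_truth")
  meta <- list(
    ground_truth = gt,
    sampling_rate_hz = attr(obj, "sampling_rate_hz"),
    pre_s = attr(obj, "pre_s"), stim_s = attr(obj, "stim_s"),
    post_s = attr(obj, "post_s"),
    frame_rate_hz = attr(obj, "frame_rate_hz"),
    stimulus = unclass(attr(obj, "stimulus")))
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
}

#' @rdname okr_io
#' @export
write_eye_trace <- function(trace, path, sidecar = TRUE) {
  utils::write.csv(trace[, c("time_s", "position_deg")], path,
                   row.names = FALSE)
  if (sidecar) write_sidecar(trace, path)
  invisible(path)
}

#' @rdname okr_io
#' @param stim Stimulus to attach when the sidecar is absent.
#' @export
read_eye_trace <- function(path, stim = NULL) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(meta$sampling_rate_hz))
      attr(df, "sampling_rate_hz") <- meta$sampling_rate_hz
    if (is.null(stim) && !is.null(meta$stimulus))
      stim <- do.call(drum_stimulus, meta$stimulus[
        c("mode", "amplitude_deg", "oscillation_freq_hz", "sf_cpd",
          "duration_s", "pre_s", "post_s", "direction_deg")])
  }
  if (is.null(attr(df, "sampling_rate_hz")))
    attr(df, "sampling_rate_hz") <- 1 / (df$time_s[2L] - df$time_s[1L])
  attr(df, "stimulus") <- stim
  class(df) <- c("eye_trace", "data.frame")
  df
}

#' @rdname okr_io
#' @export
write_trial_table <- function(trials, path, sidecar = TRUE) {
  utils::write.csv(
    trials[, c("neuron_id", "direction_deg", "trial", "time_s", "F")],
    path, row.names = FALSE)
  if (sidecar) write_sidecar(trials, path)
  invisible(path)
}

#' @rdname okr_io
#' @export
read_trial_table <- function(path) {
  df <- utils::read.csv(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (a in c("pre_s", "stim_s", "post_s", "frame_rate_hz"))
      if (!is.null(meta[[a]])) attr(df, a) <- meta[[a]]
  }
  class(df) <- c("trial_set", "data.frame")
  df
}

#' @rdname okr_io
#' @export
write_cell_map <- function(map, path, sidecar = FALSE) {
  utils::write.csv(map[, c("x_um", "y_um", "area")], path,
                   row.names = FALSE)
  if (sidecar) write_sidecar(map, path)
  invisible(path)
}

#' @rdname okr_io
#' @export
read_cell_map <- function(path) {
  df <- utils::read.csv(path, colClasses = c("numeric", "numeric",
                                             "character"))
  class(df) <- c("cell_map", "data.frame")
  df
}
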