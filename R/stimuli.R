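#' Describe the drum grating stimulus
#'
#' Parametric description of the "virtual drum" grating used to drive the
#' horizontal OKR. In oscillatory mode the grating rotates sinusoidally
#' about its start position; in unidirectional mode it drifts at constant
#' speed, with the temporal frequency and spatial frequency together
#' setting the angular velocity (deg/s = tf / sf).
#'
#' @param mode "oscillatory" or "unidirectional".
#' @param amplitude_deg Peak oscillation amplitude in degrees (oscillatory
#'   mode). The standard protocol uses +/- 5 degrees.
#' @param oscillation_freq_hz Oscillation frequency in Hz (oscillatory
#'   mode) or temporal frequency in Hz (unidirectional mode). Default 0.4.
#' @param sf_cpd Spatial frequency in cycles/degree.
#' @param duration_s Stimulation duration in seconds.
#' @param pre_s,post_s Seconds of blank (stationary) padding before and
#'   after the stimulation window.
#' @param direction_deg Drift direction in degrees for unidirectional
#'   mode; 0 is temporo-nasal, 180 naso-temporal.
#' @return An object of class `drum_stimulus`.
#' @export
drum_stimulus <- function(mode = c("oscillatory", "unidirectional"),
                          amplitude_deg = 5,
                          oscillation_freq_hz = 0.4,
                          sf_cpd = 0.1,
                          duration_s = 10,
                          pre_s = 1,
                          post_s = 1,
                          direction_deg = 0) {
  mode <- match.arg(mode)
  if (mode == "oscillatory" && amplitude_deg <= 0)
    stop("amplitude_deg must be > 0 in oscillatory mode")
  if (oscillation_freq_hz <= 0) stop("oscillation_freq_hz must be > 0")
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (pre_s < 0 || post_s < 0) stop("padding must be non-negative")
  structure(
    list(mode = mode, amplitude_deg = amplitude_deg,
         oscillation_freq_hz = oscillation_freq_hz, sf_cpd = sf_cpd,
         duration_s = duration_s, pre_s = pre_s, post_s = post_s,
         direction_deg = direction_deg),
    class = "drum_stimulus")
}

#' @export
print.drum_stimulus <- function(x, ...) {
  cat(sprintf("<drum_stimulus> %s", x$mode))
  if (x$mode == "oscillatory")
    cat(sprintf(", +/-%g deg at %g Hz", x$amplitude_deg, x$oscillation_freq_hz))
  else
    cat(sprintf(", %g deg toward %g deg", drum_speed(x) * x$duration_s,
                x$direction_deg))
  cat(sprintf(", %g s stim (%g s pre / %g s post), SF %g cpd\n",
              x$duration_s, x$pre_s, x$post_s, x$sf_cpd))
  invisible(x)
}

# angular drift speed (deg/s) of a unidirectional drum
drum_speed <- function(stim) stim$oscillation_freq_hz / stim$sf_cpd

#' Drum position at arbitrary times
#'
#' Evaluates the drum trajectory analytically. Position is zero in the
#' pre/post padding; during stimulation it is `A sin(2 pi f t')` with
#' `t'` the time since stimulus onset (oscillatory mode), or a constant-
#' velocity ramp (unidirectional mode; positive along 0 deg,
#' temporo-nasal).
#'
#' @param stim A [drum_stimulus()].
#' @param time_s Numeric vector of times in seconds (0 = trace start).
#' @return Numeric vector of positions in degrees.
#' @export
drum_position <- function(stim, time_s) {
  t_rel <- pmin(pmax(time_s - stim$pre_s, 0), stim$duration_s)
  if (stim$mode == "oscillatory") {
    pos <- stim$amplitude_deg * sin(2 * pi * stim$oscillation_freq_hz * t_rel)
    # outside the stimulation window the drum is stationary at 0
    pos[time_s < stim$pre_s | time_s > stim$pre_s + stim$duration_s] <- 0
    pos
  } else {
    sgn <- cos(stim$direction_deg * pi / 180)
    sgn * drum_speed(stim) * t_rel
  }
}

#' Sample the drum trajectory on a uniform grid
#'
#' @param stim A [drum_stimulus()].
#' @param sampling_rate_hz Sampling rate in Hz.
#' @return A data frame with columns `time_s` and `position_deg` covering
#'   `pre_s + duration_s + post_s` seconds
#'   (`round(total * rate) + 1` samples).
#' @export
gen_drum_trajectory <- function(stim, sampling_rate_hz = 100) {
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0")
  total <- stim$pre_s + stim$duration_s + stim$post_s
  n <- round(total * sampling_rate_hz) + 1L
  t <- (seq_len(n) - 1L) / sampling_rate_hz
  data.frame(time_s = t, position_deg = drum_position(stim, t))
}
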