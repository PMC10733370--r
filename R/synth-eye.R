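#' Specification of a synthetic eye trace
#'
#' Collects the generative parameters of a simulated video-oculography
#' recording: a tracking gain and lag relative to the drum, slow drift,
#' saccade-like steps at Poisson-distributed times, and Gaussian
#' measurement noise. The 100 Hz default matches standard infrared
#' video-oculography.
#'
#' @param true_gain Tracking gain (eye amplitude / drum amplitude), >= 0.
#' @param lag_s Tracking lag in seconds.
#' @param saccade_rate_hz Expected saccade rate in events/s.
#' @param saccade_amp_deg Saccade step amplitude in degrees (signs are
#'   drawn at random).
#' @param drift_deg_per_s Linear drift in degrees/s.
#' @param noise_sd_deg Gaussian measurement noise SD in degrees.
#' @param sampling_rate_hz Sampling rate, default 100 Hz.
#' @return An object of class `eye_spec`.
#' @export
eye_spec <- function(true_gain = 0.6, lag_s = 0, saccade_rate_hz = 0,
                     saccade_amp_deg = 8, drift_deg_per_s = 0,
                     noise_sd_deg = 0, sampling_rate_hz = 100) {
  if (true_gain < 0) stop("true_gain must be >= 0")
  if (sampling_rate_hz <= 0) stop("sampling_rate_hz must be > 0")
  if (noise_sd_deg < 0 || saccade_rate_hz < 0)
    stop("noise and saccade rate must be >= 0")
  structure(
    list(true_gain = true_gain, lag_s = lag_s,
         saccade_rate_hz = saccade_rate_hz,
         saccade_amp_deg = saccade_amp_deg,
         drift_deg_per_s = drift_deg_per_s, noise_sd_deg = noise_sd_deg,
         sampling_rate_hz = sampling_rate_hz),
    class = "eye_spec")
}

#' Generate a synthetic eye-position trace
#'
#' Simulates an eye tracking the drum with a given gain and lag, plus
#' drift, Gaussian noise, and saccade-like steps. Each saccade is a step
#' of `saccade_amp_deg` (random sign) completed within 3 samples
#' (<= 30 ms at 100 Hz), a worst case for velocity-based detection and
#' interpolation. The generative parameters are stored on the returned
#' object so downstream estimators can be scored for recovery.
#'
#' @param stim A [drum_stimulus()].
#' @param spec An [eye_spec()].
#' @param seed Integer seed; fully determines the output.
#' @return An `eye_trace`: data frame with `time_s`, `position_deg`, and
#'   attributes `sampling_rate_hz`, `stimulus`, `ground_truth`.
#' @export
gen_eye_trace <- function(stim, spec, seed = 1L) {
  if (spec$sampling_rate_hz <= 2 * stim$oscillation_freq_hz)
    stop("sampling rate must exceed twice the oscillation frequency")
  set.seed(seed)
  rate <- spec$sampling_rate_hz
  total <- stim$pre_s + stim$duration_s + stim$post_s
  n <- round(total * rate) + 1L
  t <- (seq_len(n) - 1L) / rate

  pos <- spec$true_gain * drum_position(stim, t - spec$lag_s) +
    spec$drift_deg_per_s * t

  saccade_times <- numeric(0)
  saccade_signs <- numeric(0)
  if (spec$saccade_rate_hz > 0) {
    n_sac <- stats::rpois(1L, spec$saccade_rate_hz * total)
    if (n_sac > 0) {
      saccade_times <- sort(stats::runif(n_sac, 0, total))
      saccade_signs <- sample(c(-1, 1), n_sac, replace = TRUE)
      dt <- 1 / rate
      for (j in seq_len(n_sac)) {
        # linear ramp over 2 sample intervals, then a completed step
        frac <- pmin(pmax((t - saccade_times[j]) / (2 * dt), 0), 1)
        pos <- pos + saccade_signs[j] * spec$saccade_amp_deg * frac
      }
    }
  }
  if (spec$noise_sd_deg > 0)
    pos <- pos + stats::rnorm(n, 0, spec$noise_sd_deg)

  out <- data.frame(time_s = t, position_deg = pos)
  attr(out, "sampling_rate_hz") <- rate
  attr(out, "stimulus") <- stim
  attr(out, "ground_truth") <- list(spec = spec, seed = seed,
                                    saccade_times_s = saccade_times,
                                    saccade_signs = saccade_signs)
  class(out) <- c("eye_trace", "data.frame")
  out
}
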