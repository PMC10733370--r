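#' Detect and remove saccade-like fast eye movements
#'
#' Saccades are detected as surges in the velocity curve (central-
#' difference temporal derivative of eye position) exceeding a
#' threshold, padded by `pad_samples` on each side. The flagged samples
#' are replaced by linear interpolation of the velocity between the
#' flanking clean samples, and the position is reintegrated, so that
#' both the fast movement and its displacement are removed and only
#' slow eye movements remain. Flagged samples at the trace boundaries
#' take the velocity of the nearest clean sample (flat extrapolation).
#'
#' The default threshold of 25 deg/s sits an order of magnitude above the
#' peak slow-phase velocity of 5-degree, 0.4 Hz tracking
#' (2 pi f A ~ 12.6 deg/s times a gain well below 1) and well below
#' saccadic velocities.
#'
#' @param trace An `eye_trace` (data frame with `time_s`, `position_deg`).
#' @param velocity_threshold_deg_per_s Velocity threshold in deg/s.
#' @param pad_samples Samples of padding flagged on each side of a
#'   suprathreshold excursion.
#' @return The trace with interpolated `position_deg` and a logical
#'   attribute `saccade_mask` marking replaced samples.
#' @export
remove_saccades <- function(trace, velocity_threshold_deg_per_s = 25,
                            pad_samples = 2L) {
  if (velocity_threshold_deg_per_s <= 0) stop("threshold must be > 0")
  x <- trace$position_deg
  t <- trace$time_s
  n <- length(x)
  if (n < 3L) stop("trace too short")
  dt <- t[2L] - t[1L]

  v <- numeric(n)
  v[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  v[1L] <- (x[2L] - x[1L]) / dt
  v[n] <- (x[n] - x[n - 1L]) / dt

  mask <- abs(v) > velocity_threshold_deg_per_s
  if (pad_samples > 0L && any(mask)) {
    idx <- which(mask)
    for (k in seq_len(pad_samples))
      mask[pmax(idx - k, 1L)] <- mask[pmin(idx + k, n)] <- TRUE
  }
  if (all(mask)) stop("every sample flagged as saccadic; trace unusable")

  if (any(mask)) {
    # interpolate the forward-difference velocity across flagged
    # samples, then reintegrate: removes the saccadic displacement,
    # not just the fast samples
    vf <- (x[-1L] - x[-n]) / dt
    vmask <- mask[-n] | mask[-1L]
    clean <- which(!vmask)
    vf[vmask] <- stats::approx(t[clean], vf[clean], xout = t[-n][vmask],
                               rule = 2)$y
    x <- x[1L] + c(0, cumsum(vf)) * dt
  }
  out <- trace
  out$position_deg <- x
  attr(out, "saccade_mask") <- mask
  out
}

#' OKR gain from the Fourier amplitude ratio
#'
#' Computes the optokinetic-reflex gain as the ratio of the eye-movement
#' amplitude to the drum-movement amplitude at the oscillation frequency:
#' gain = Amp_eye / Amp_drum. Both amplitudes are single-bin discrete
#' Fourier projections `2/M |sum x(t_i) exp(-i 2 pi f t_i)|` over an
#' integer number of stimulus cycles (leakage-free), after saccade
#' removal and mean subtraction. A perfectly tracking eye yields gain 1
#' and a motionless eye yields gain 0. Interpolated (formerly saccadic)
#' samples are retained in the analysis window.
#'
#' @param trace An `eye_trace`.
#' @param stim The oscillatory [drum_stimulus()]; defaults to the
#'   stimulus attached to the trace.
#' @param desaccade Apply [remove_saccades()] first (default TRUE).
#' @param velocity_threshold_deg_per_s,pad_samples Passed to
#'   [remove_saccades()].
#' @param window_cycles Number of stimulus cycles analyzed; default all
#'   complete cycles within the stimulation period.
#' @return A `gain_result` list: `gain`, `amp_eye_deg`, `amp_drum_deg`,
#'   `n_cycles_used`, `saccade_fraction`.
#' @export
okr_gain <- function(trace, stim = attr(trace, "stimulus"),
                     desaccade = TRUE,
                     velocity_threshold_deg_per_s = 25, pad_samples = 2L,
                     window_cycles = NULL) {
  if (is.null(stim)) stop("no stimulus attached to trace; supply `stim`")
  if (stim$mode != "oscillatory")
    stop("okr_gain requires an oscillatory stimulus; see unidirectional_gain")
  f <- stim$oscillation_freq_hz
  rate <- attr(trace, "sampling_rate_hz")
  if (is.null(rate)) rate <- 1 / (trace$time_s[2L] - trace$time_s[1L])

  sac_frac <- 0
  if (desaccade) {
    trace <- remove_saccades(trace, velocity_threshold_deg_per_s,
                             pad_samples)
    sac_frac <- mean(attr(trace, "saccade_mask"))
  }

  n_cyc <- floor(stim$duration_s * f)
  if (!is.null(window_cycles)) n_cyc <- min(n_cyc, window_cycles)
  if (n_cyc < 1L) stop("fewer than one full stimulus cycle available")
  m <- round(n_cyc / f * rate)
  i0 <- which(trace$time_s >= stim$pre_s - 1e-9)[1L]
  if (is.na(i0) || i0 + m - 1L > nrow(trace))
    stop("trace does not cover the analysis window")
  idx <- i0 + seq_len(m) - 1L

  amp_eye <- fourier_amp(trace$position_deg[idx], trace$time_s[idx], f)
  drum <- drum_position(stim, trace$time_s[idx])
  amp_drum <- fourier_amp(drum, trace$time_s[idx], f)

  structure(
    list(gain = amp_eye / amp_drum, amp_eye_deg = amp_eye,
         amp_drum_deg = amp_drum, n_cycles_used = n_cyc,
         saccade_fraction = sac_frac),
    class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf(
    "<gain_result> gain = %.4f (Amp_eye %.3f deg / Amp_drum %.3f deg, %d cycles, %.1f%% samples interpolated)\n",
    x$gain, x$amp_eye_deg, x$amp_drum_deg, x$n_cycles_used,
    100 * x$saccade_fraction))
  invisible(x)
}

# single-bin DFT amplitude at frequency f after mean subtraction
fourier_amp <- function(x, t, f) {
  x <- x - mean(x)
  m <- length(x)
  2 / m * Mod(sum(x * exp(-1i * 2 * pi * f * t)))
}

#' Slow-phase gain for unidirectional drum drift
#'
#' For a unidirectionally drifting drum the eye shows nystagmus: slow
#' tracking phases interleaved with fast resetting movements. The fast
#' phases are removed with the same velocity-threshold operator used for
#' oscillatory trials, and the gain is the slope of a linear fit of the
#' desaccaded eye position over the stimulation window divided by the
#' drum angular velocity.
#'
#' @inheritParams okr_gain
#' @return A list with `gain`, `slow_phase_velocity_deg_per_s`,
#'   `stimulus_velocity_deg_per_s`.
#' @export
unidirectional_gain <- function(trace, stim = attr(trace, "stimulus"),
                                velocity_threshold_deg_per_s = 25,
                                pad_samples = 2L) {
  if (is.null(stim) || stim$mode != "unidirectional")
    stop("unidirectional_gain requires a unidirectional stimulus")
  trace <- remove_saccades(trace, velocity_threshold_deg_per_s, pad_samples)
  in_win <- trace$time_s >= stim$pre_s &
    trace$time_s <= stim$pre_s + stim$duration_s
  fit <- stats::lm.fit(cbind(1, trace$time_s[in_win]),
                       trace$position_deg[in_win])
  v_eye <- fit$coefficients[2L]
  v_stim <- cos(stim$direction_deg * pi / 180) * drum_speed(stim)
  list(gain = unname(v_eye / v_stim),
       slow_phase_velocity_deg_per_s = unname(v_eye),
       stimulus_velocity_deg_per_s = v_stim)
}

#' Cortical contribution to OKR gain
#'
#' Percentage reduction in OKR gain caused by cortical silencing:
#' `delta_v = 100 (V_control - V_silencing) / V_control`. Recordings with
#' a control gain below 0.02 are flagged as excluded from summaries.
#' A silencing gain above the control gain yields a negative value
#' (suppression-to-enhancement sign convention).
#'
#' @param v_control OKR gain under control conditions (> 0).
#' @param v_silencing OKR gain during cortical silencing (>= 0).
#' @return A `contribution_result` list: `v_control`, `v_silencing`,
#'   `delta_v_pct`, `included`.
#' @export
cortical_contribution <- function(v_control, v_silencing) {
  if (any(v_control < 0) || any(v_silencing < 0))
    stop("gains must be >= 0")
  if (any(v_control == 0))
    stop("v_control is 0; contribution undefined")
  structure(
    list(v_control = v_control, v_silencing = v_silencing,
         delta_v_pct = 100 * (v_control - v_silencing) / v_control,
         included = v_control >= 0.02),
    class = "contribution_result")
}

#' OKR potentiation
#'
#' Fractional change in OKR gain after the induction protocol:
#' `(V_post - V_pre) / V_pre`.
#'
#' @param v_pre Gain before induction (> 0).
#' @param v_post Gain after induction (>= 0).
#' @return Dimensionless fractional change.
#' @export
okr_potentiation <- function(v_pre, v_post) {
  if (any(v_pre <= 0)) stop("v_pre must be > 0")
  (v_post - v_pre) / v_pre
}
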