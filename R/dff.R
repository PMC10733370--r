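#' Fractional fluorescence change per trial
#'
#' Computes dF/F = (F_I - F_0) / F_0 per sample, where F_0 is the mean
#' fluorescence over the baseline window (the 1 s prior to visual
#' stimulation by default) of the same trial.
#'
#' @param trials A `trial_set` (see [gen_calcium_trials()]) or a long
#'   data frame with `neuron_id`, `direction_deg`, `trial`, `time_s`,
#'   `F`.
#' @param pre_s Baseline window length in seconds (stimulus onset is at
#'   `pre_s`); defaults to the trial set's attribute.
#' @return The input with an added `dff` column.
#' @export
compute_dff <- function(trials, pre_s = attr(trials, "pre_s")) {
  if (is.null(pre_s)) pre_s <- 1
  dir_key <- ifelse(is.na(trials$direction_deg), "blank",
                    as.character(trials$direction_deg))
  key <- interaction(trials$neuron_id, dir_key, trials$trial, drop = TRUE)
  fb <- ifelse(trials$time_s < pre_s, trials$F, NA_real_)
  f0 <- stats::ave(fb, key, FUN = function(z) mean(z, na.rm = TRUE))
  if (any(f0 <= 0))
    stop("non-positive baseline fluorescence F_0; dF/F undefined")
  trials$dff <- (trials$F - f0) / f0
  trials
}

#' Per-trial response amplitudes
#'
#' The response amplitude of a trial is the mean dF/F over the
#' stimulation window.
#'
#' @param trials A `trial_set` with a `dff` column (see [compute_dff()];
#'   applied automatically if absent).
#' @param pre_s,stim_s Stimulation window `[pre_s, pre_s + stim_s)`.
#' @return Data frame `neuron_id`, `direction_deg`, `trial`, `amp`.
#' @export
trial_amplitudes <- function(trials, pre_s = attr(trials, "pre_s"),
                             stim_s = attr(trials, "stim_s")) {
  if (is.null(trials$dff)) trials <- compute_dff(trials, pre_s)
  if (is.null(pre_s)) pre_s <- 1
  if (is.null(stim_s)) stop("stimulation window length unknown")
  w <- trials$time_s >= pre_s & trials$time_s < pre_s + stim_s
  sub <- trials[w, , drop = FALSE]
  agg <- stats::aggregate(
    sub$dff,
    by = list(neuron_id = sub$neuron_id,
              direction_deg = ifelse(is.na(sub$direction_deg), Inf,
                                     sub$direction_deg),
              trial = sub$trial),
    FUN = mean)
  names(agg)[4L] <- "amp"
  agg$direction_deg[is.infinite(agg$direction_deg)] <- NA_real_
  agg[order(agg$neuron_id, agg$direction_deg, agg$trial), , drop = FALSE]
}

#' Tukey-fence outlier-trial removal
#'
#' Drops trials whose amplitude lies above the upper quartile or below
#' the lower quartile by at least 1.5 times the interquartile range.
#' Quartiles use linear-interpolation (type 7) quantiles. With fewer
#' than 4 trials the fences are not defined and all trials are retained.
#'
#' @param amplitudes Numeric vector of per-trial amplitudes for one
#'   stimulus condition.
#' @param k Fence multiplier, default 1.5.
#' @return Logical vector, `TRUE` for retained trials.
#' @export
remove_outlier_trials <- function(amplitudes, k = 1.5) {
  n <- length(amplitudes)
  if (n < 4L) return(rep(TRUE, n))
  q <- stats::quantile(amplitudes, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  amplitudes >= q[1L] - k * iqr & amplitudes <= q[2L] + k * iqr
}

#' Tuning curves with responsiveness classification
#'
#' Trial-averages response amplitudes per stimulus after Tukey outlier
#' removal, and classifies each neuron as visually responsive when
#' (1) its maximum trial-averaged amplitude is at least
#' `amp_threshold` (6% dF/F by default) and (2) the per-trial amplitudes
#' at the preferred (maximal) stimulus are significantly higher than
#' those of blank trials (two-sample t-test, one threshold p < 0.05).
#' Without blank trials the test cannot run and `responsive` is `NA`.
#'
#' @param trials A `trial_set`, or a precomputed amplitude table from
#'   [trial_amplitudes()].
#' @param amp_threshold Minimum peak amplitude, default 0.06.
#' @param p_threshold Significance threshold, default 0.05.
#' @return A `tuning_table` data frame with one row per neuron and
#'   stimulus (`neuron_id`, `direction_deg`, `R`, `n_trials`) plus an
#'   attribute `neurons`: per-neuron summary (`neuron_id`, `max_amp`,
#'   `p_blank`, `responsive`).
#' @export
tuning_curves <- function(trials, amp_threshold = 0.06,
                          p_threshold = 0.05) {
  amps <- if (!is.null(trials$amp)) trials else trial_amplitudes(trials)

  out <- list(); summ <- list()
  for (id in unique(amps$neuron_id)) {
    a <- amps[amps$neuron_id == id, , drop = FALSE]
    stim_vals <- unique(a$direction_deg)
    kept <- lapply(stim_vals, function(d) {
      sel <- if (is.na(d)) is.na(a$direction_deg) else
        !is.na(a$direction_deg) & a$direction_deg == d
      x <- a$amp[sel]
      x[remove_outlier_trials(x)]
    })
    names(kept) <- as.character(stim_vals)
    r <- vapply(kept, mean, numeric(1))
    n <- vapply(kept, length, integer(1))

    non_blank <- !is.na(stim_vals)
    max_amp <- max(r[non_blank])
    pref_idx <- which(non_blank)[which.max(r[non_blank])]
    p_blank <- NA_real_
    if (any(!non_blank)) {
      blank <- kept[[which(!non_blank)[1L]]]
      pref <- kept[[pref_idx]]
      if (length(blank) >= 2 && length(pref) >= 2)
        p_blank <- tryCatch(
          stats::t.test(pref, blank, alternative = "greater")$p.value,
          # degenerate (constant) data: decide by the means alone
          error = function(e) as.numeric(mean(pref) <= mean(blank)))
    }
    responsive <- if (is.na(p_blank)) NA else
      (max_amp >= amp_threshold && p_blank < p_threshold)

    out[[length(out) + 1L]] <- data.frame(
      neuron_id = id, direction_deg = stim_vals, R = unname(r),
      n_trials = unname(n))
    summ[[length(summ) + 1L]] <- data.frame(
      neuron_id = id, max_amp = max_amp, p_blank = p_blank,
      responsive = responsive)
  }
  res <- do.call(rbind, out)
  attr(res, "neurons") <- do.call(rbind, summ)
  class(res) <- c("tuning_table", "data.frame")
  res
}

#' Nonnegative deconvolution of a calcium trace
#'
#' Inverts the first-order exponential calcium kernel (decay constant
#' `kernel_tau_s`, unit DC gain) by autoregressive inversion,
#' `r[k] = (y[k] - g y[k-1]) / (1 - g)` with `g = exp(-dt / tau)`, then
#' truncates negative values at zero. Re-convolving the untruncated
#' estimate reproduces the input exactly; truncation only acts on noise-
#' or mismatch-driven negative excursions.
#'
#' @param dff Numeric dF/F trace, uniformly sampled.
#' @param kernel_tau_s Kernel decay constant in seconds (default 1.5,
#'   appropriate for GCaMP6s).
#' @param frame_rate_hz Sampling rate in Hz.
#' @return Nonnegative rate estimate (same length and units/frame).
#' @export
deconvolve_calcium <- function(dff, kernel_tau_s = 1.5,
                               frame_rate_hz = 10) {
  if (kernel_tau_s <= 0) stop("kernel_tau_s must be > 0")
  g <- exp(-1 / (frame_rate_hz * kernel_tau_s))
  n <- length(dff)
  r <- (dff - g * c(0, dff[-n])) / (1 - g)
  pmax(r, 0)
}
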