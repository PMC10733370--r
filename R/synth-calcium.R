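#' Specification of a direction-tuned synthetic neuron
#'
#' @param pref_direction_deg Preferred direction in degrees, [0, 360).
#' @param tuning_width_deg Tuning width (approximate circular SD of each
#'   von Mises lobe) in degrees.
#' @param peak_amp Peak response amplitude at the preferred direction, in
#'   the same units as the fluorescence baseline (so the peak dF/F equals
#'   `peak_amp / baseline` up to kernel filtering) or in spikes/s.
#' @param dir_null_ratio Response at pref + 180 deg relative to the
#'   preferred response, in [0, 1]. Sets DSI = (1 - r) / (1 + r).
#' @param baseline Baseline fluorescence (or spontaneous rate).
#' @param plasticity_factor Multiplicative factor applied to the tuned
#'   response in post-induction sessions (> 0).
#' @return An object of class `neuron_spec`.
#' @export
neuron_spec <- function(pref_direction_deg, tuning_width_deg = 30,
                        peak_amp = 0.3, dir_null_ratio = 0.4,
                        baseline = 1, plasticity_factor = 1) {
  if (peak_amp < 0) stop("peak_amp must be >= 0")
  if (dir_null_ratio < 0 || dir_null_ratio > 1)
    stop("dir_null_ratio must be in [0, 1]")
  if (plasticity_factor <= 0) stop("plasticity_factor must be > 0")
  structure(
    list(pref_direction_deg = pref_direction_deg %% 360,
         tuning_width_deg = tuning_width_deg, peak_amp = peak_amp,
         dir_null_ratio = dir_null_ratio, baseline = baseline,
         plasticity_factor = plasticity_factor),
    class = "neuron_spec")
}

#' Double von Mises direction tuning
#'
#' Tuning shape with a primary lobe at the preferred direction and a
#' secondary lobe at pref + 180 deg scaled by `dir_null_ratio`, each a
#' von Mises bump `exp(kappa (cos(theta - mu) - 1))` with
#' `kappa = (180 / (pi w))^2` so that `w` approximates the circular SD
#' in degrees. Yields controllable DSI in closed form:
#' for narrow lobes DSI = (1 - r) / (1 + r).
#'
#' @param direction_deg Stimulus direction(s) in degrees.
#' @param neuron A [neuron_spec()].
#' @return Relative response in [0, 1 + small cross-lobe term].
#' @export
tuning_shape <- function(direction_deg, neuron) {
  kappa <- (180 / (pi * neuron$tuning_width_deg))^2
  vm <- function(mu) exp(kappa * (cos((direction_deg - mu) * pi / 180) - 1))
  vm(neuron$pref_direction_deg) +
    neuron$dir_null_ratio * vm(neuron$pref_direction_deg + 180)
}

#' Sample a population of neuron specs with a given direction bias
#'
#' Draws preferred directions from a categorical distribution over the
#' sampled directions (for example the temporo-nasally enriched
#' composition of NOT-DTN-projecting pyramidal neurons, or the flat
#' composition of midbrain-projecting neurons), with small angular
#' scatter, and applies group-specific multiplicative plasticity.
#'
#' @param n_neurons Number of neurons.
#' @param group_fractions Named fractions per sampled direction (names
#'   are directions in degrees); must sum to 1.
#' @param directions Sampled directions the fractions refer to.
#' @param plasticity_factors Optional named vector (same names as
#'   `group_fractions`) of multiplicative post/pre factors per group.
#' @param tuning_width_deg,dir_null_ratio,peak_amp,baseline Passed to
#'   [neuron_spec()]; `peak_amp` may be length `n_neurons`.
#' @param jitter_deg SD of angular scatter of preferred directions about
#'   the group direction.
#' @param seed Integer seed.
#' @return List of `neuron_spec` objects with a `group` attribute each.
#' @export
sample_population <- function(n_neurons, group_fractions,
                              directions = as.numeric(names(group_fractions)),
                              plasticity_factors = NULL,
                              tuning_width_deg = 30, dir_null_ratio = 0.4,
                              peak_amp = 0.3, baseline = 1,
                              jitter_deg = 10, seed = 1L) {
  if (abs(sum(group_fractions) - 1) > 1e-9)
    stop("group_fractions must sum to 1")
  set.seed(seed)
  g <- sample(seq_along(directions), n_neurons, replace = TRUE,
              prob = group_fractions)
  prefs <- (directions[g] + stats::rnorm(n_neurons, 0, jitter_deg)) %% 360
  peak <- rep_len(peak_amp, n_neurons)
  lapply(seq_len(n_neurons), function(i) {
    pf <- if (is.null(plasticity_factors)) 1 else plasticity_factors[g[i]]
    ns <- neuron_spec(prefs[i], tuning_width_deg, peak[i], dir_null_ratio,
                      baseline, pf)
    attr(ns, "group") <- directions[g[i]]
    ns
  })
}

#' Generate trial-structured synthetic calcium recordings
#'
#' Emulates two-photon recordings of direction-tuned neurons: each trial
#' is sampled at `frame_rate_hz` and covers 1 s of baseline, a
#' stimulation window, and post-stimulus padding. The underlying rate is
#' the tuned amplitude during stimulation, low-pass filtered by a
#' first-order exponential calcium kernel (tau = 1.5 s for GCaMP6s) with
#' unit DC gain; fluorescence = baseline + filtered rate + Gaussian
#' noise. In post-induction sessions the tuned rate is multiplied by each
#' neuron's `plasticity_factor`. Blank (grey screen) trials are included
#' with stimulus label `NA`.
#'
#' @param neurons List of [neuron_spec()] objects.
#' @param directions Stimulus directions in degrees (evenly spaced).
#' @param n_trials Trials per stimulus (>= 2).
#' @param kernel_tau_s Calcium kernel decay constant, default 1.5 s.
#' @param frame_rate_hz Imaging frame rate, default 10 Hz.
#' @param noise_sd Gaussian noise SD in fluorescence units.
#' @param seed Integer seed.
#' @param phase "pre" or "post" (post applies the plasticity factors).
#' @param pre_s,stim_s,post_s Trial structure in seconds (defaults 1, 3,
#'   1: recording starts 1 s before a 3-s stimulation).
#' @param blank_trials Number of blank trials (default `n_trials`).
#' @return A `trial_set`: long data frame (`neuron_id`, `direction_deg`,
#'   `trial`, `time_s`, `F`) with attributes `pre_s`, `stim_s`, `post_s`,
#'   `frame_rate_hz`, `phase`, `ground_truth` (the neuron list).
#' @export
gen_calcium_trials <- function(neurons, directions = seq(0, 315, by = 45),
                               n_trials = 15, kernel_tau_s = 1.5,
                               frame_rate_hz = 10, noise_sd = 0.02,
                               seed = 1L, phase = c("pre", "post"),
                               pre_s = 1, stim_s = 3, post_s = 1,
                               blank_trials = n_trials) {
  phase <- match.arg(phase)
  if (length(neurons) == 0) stop("empty neuron list")
  if (n_trials < 2) stop("need at least 2 trials per stimulus")
  if (kernel_tau_s <= 0) stop("kernel_tau_s must be > 0")
  set.seed(seed)

  dt <- 1 / frame_rate_hz
  t <- seq(0, pre_s + stim_s + post_s, by = dt)
  nt <- length(t)
  stim_on <- t >= pre_s & t < pre_s + stim_s
  g <- exp(-dt / kernel_tau_s)

  filter_rate <- function(amp) {
    # unit-DC-gain first-order low-pass of the stimulus boxcar
    r <- amp * stim_on
    stats::filter((1 - g) * r, g, method = "recursive")
  }

  stim_labels <- c(directions, NA_real_)
  trials_per <- c(rep(n_trials, length(directions)), blank_trials)
  blocks <- vector("list", length(neurons) * length(stim_labels))
  bi <- 0L
  for (i in seq_along(neurons)) {
    nr <- neurons[[i]]
    fac <- if (phase == "post") nr$plasticity_factor else 1
    for (s in seq_along(stim_labels)) {
      d <- stim_labels[s]
      amp <- if (is.na(d)) 0 else fac * nr$peak_amp * tuning_shape(d, nr)
      ntr <- trials_per[s]
      if (ntr == 0) next
      sig <- nr$baseline + as.numeric(filter_rate(amp))
      fmat <- matrix(rep(sig, ntr), nrow = nt)
      if (noise_sd > 0)
        fmat <- fmat + matrix(stats::rnorm(nt * ntr, 0, noise_sd), nrow = nt)
      bi <- bi + 1L
      blocks[[bi]] <- data.frame(
        neuron_id = i, direction_deg = d,
        trial = rep(seq_len(ntr), each = nt),
        time_s = rep(t, ntr), F = as.numeric(fmat))
    }
  }
  out <- do.call(rbind, blocks)
  attr(out, "pre_s") <- pre_s
  attr(out, "stim_s") <- stim_s
  attr(out, "post_s") <- post_s
  attr(out, "frame_rate_hz") <- frame_rate_hz
  attr(out, "kernel_tau_s") <- kernel_tau_s
  attr(out, "phase") <- phase
  attr(out, "ground_truth") <- list(neurons = neurons, seed = seed,
                                    noise_sd = noise_sd)
  class(out) <- c("trial_set", "data.frame")
  out
}
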