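#' Build a model bank from trial-structured calcium recordings
#'
#' Runs the full estimation pipeline behind the feedforward model:
#' computes tuning curves from the trial set, assigns each neuron to a
#' direction group (TN/UP/NT/DN) by its sampled preferred direction,
#' deconvolves the trial-averaged dF/F response to the temporo-nasal
#' probe direction into a firing-rate trace per neuron, and assembles
#' per-group rate templates (peak-normalized, group-averaged, scaled to
#' the population mean rate, baseline-subtracted). The bank's
#' composition is the observed group histogram unless overridden.
#'
#' @param trials A `trial_set` from [gen_calcium_trials()] (or read via
#'   [read_trial_table()]).
#' @param plasticity Named dR per group (e.g. [notdtn_plasticity()]).
#' @param probe_direction_deg Probe direction whose response drives the
#'   model, default 0 (temporo-nasal).
#' @param population_mean_rate Mean rate the scaled templates attain.
#' @param composition Optional named fractions overriding the observed
#'   group histogram.
#' @param responsive_only Use only neurons classified responsive when
#'   blank trials allow the classification (default TRUE).
#' @return A [template_bank()].
#' @export
bank_from_trials <- function(trials, plasticity,
                             probe_direction_deg = 0,
                             population_mean_rate = 10,
                             composition = NULL,
                             responsive_only = TRUE) {
  trials <- compute_dff(trials)
  curves <- tuning_curves(trials)
  info <- attr(curves, "neurons")
  ids <- info$neuron_id
  if (responsive_only && !all(is.na(info$responsive))) {
    keep <- !is.na(info$responsive) & info$responsive
    if (sum(keep) >= 8L) ids <- info$neuron_id[keep]
  }

  frame_rate <- attr(trials, "frame_rate_hz")
  pre_s <- attr(trials, "pre_s")
  tau <- attr(trials, "kernel_tau_s")
  if (is.null(tau)) tau <- 1.5

  probe <- trials[!is.na(trials$direction_deg) &
                    trials$direction_deg == probe_direction_deg, ]
  tgrid <- sort(unique(probe$time_s))

  groups <- character(length(ids))
  rates <- matrix(NA_real_, length(tgrid), length(ids))
  for (j in seq_along(ids)) {
    cv <- curves[curves$neuron_id == ids[j] &
                   !is.na(curves$direction_deg), ]
    pref <- preferred_direction(cv$R, cv$direction_deg)
    groups[j] <- direction_group(pref$sampled_pref_deg)
    pb <- probe[probe$neuron_id == ids[j], ]
    avg <- vapply(split(pb$dff, pb$time_s), mean, numeric(1))
    rates[, j] <- deconvolve_calcium(avg[as.character(tgrid)], tau,
                                     frame_rate)
  }

  if (is.null(composition)) {
    tab <- table(factor(groups, levels = model_groups))
    composition <- as.numeric(tab) / sum(tab)
    names(composition) <- model_groups
  }
  templates <- build_rate_templates(rates, tgrid - pre_s, groups,
                                    plasticity, population_mean_rate)
  template_bank(templates, composition, plasticity)
}

#' Generate a synthetic model bank for one corticofugal population
#'
#' Convenience generator for scenario analyses: samples a tuned neuron
#' population with the requested direction composition and direction
#' selectivity, simulates a pre-induction calcium session, and runs
#' [bank_from_trials()]. `kind = "notdtn"` emulates the temporo-nasally
#' enriched, strongly direction-selective NOT-DTN-projecting
#' population; `kind = "midbrain"` the flat, more weakly selective
#' midbrain-projecting population.
#'
#' @param kind "notdtn" or "midbrain".
#' @param n_neurons Neurons to simulate, default 60.
#' @param n_trials Trials per direction, default 10.
#' @param noise_sd Fluorescence noise SD, default 0.02.
#' @param seed Integer seed.
#' @return A [template_bank()].
#' @export
synthetic_bank <- function(kind = c("notdtn", "midbrain"),
                           n_neurons = 60, n_trials = 10,
                           noise_sd = 0.02, seed = 1L) {
  kind <- match.arg(kind)
  comp <- if (kind == "notdtn") notdtn_composition() else
    midbrain_composition()
  plast <- if (kind == "notdtn") notdtn_plasticity() else
    midbrain_plasticity()
  # dir_null_ratio sets DSI = (1 - r)/(1 + r): ~0.43 for the strongly
  # selective population (DSI ~ 0.40), ~0.48 for the weaker one (~0.35)
  dnr <- if (kind == "notdtn") 0.43 else 0.48
  pop <- sample_population(
    n_neurons, stats::setNames(comp, c(0, 90, 180, 270)),
    dir_null_ratio = dnr, peak_amp = 0.3, seed = seed)
  trials <- gen_calcium_trials(pop, directions = c(0, 90, 180, 270),
                               n_trials = n_trials, noise_sd = noise_sd,
                               seed = seed + 1L)
  bank_from_trials(trials, plast, composition = comp)
}
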