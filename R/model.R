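#' Feedforward-model configuration
#'
#' Parameters of the firing-rate feedforward integration model of
#' cortical drive onto the NOT-DTN: the synaptic current obeys
#' `tau dI/dt = -I + sum_b w_b u_b`, with `tau` the AMPA-conductance
#' decay constant (3.9 ms), a uniform synaptic weight `w = 0.005`, and
#' `N = 100` presynaptic neurons split among the four direction groups.
#' The charge is the integral of the current over a 3.5-s window from
#' stimulus onset.
#'
#' @param tau_s Synaptic decay constant in seconds, default 0.0039.
#' @param w Uniform synaptic weight, default 0.005.
#' @param n_neurons Total presynaptic neuron count, default 100.
#' @param charge_window_s Charge-integration window in seconds from
#'   stimulus onset, default 3.5.
#' @param dt_s Integration step; must satisfy `dt_s <= tau_s / 5`.
#' @return An object of class `model_config`.
#' @export
model_config <- function(tau_s = 0.0039, w = 0.005, n_neurons = 100,
                         charge_window_s = 3.5, dt_s = tau_s / 7.8) {
  if (tau_s <= 0) stop("tau_s must be > 0")
  if (charge_window_s <= 0) stop("charge_window_s must be > 0")
  if (dt_s > tau_s / 5) stop("dt_s must be <= tau_s / 5")
  structure(list(tau_s = tau_s, w = w, n_neurons = n_neurons,
                 charge_window_s = charge_window_s, dt_s = dt_s),
            class = "model_config")
}

model_groups <- c("TN", "UP", "NT", "DN")

#' Per-group firing-rate template
#'
#' A baseline-subtracted firing-rate input for one direction group, with
#' the post-potentiation rate constructed multiplicatively from the
#' group's plasticity strength: `rate_post = rate_pre (1 + dR)`.
#'
#' @param group One of "TN", "UP", "NT", "DN".
#' @param time_s Time grid in seconds, 0 = stimulus onset.
#' @param rate_pre Baseline-subtracted pre-potentiation rate (spikes/s
#'   or deconvolved-rate units).
#' @param plasticity_strength Group dR (dimensionless).
#' @return An object of class `rate_template`.
#' @export
rate_template <- function(group, time_s, rate_pre,
                          plasticity_strength = 0) {
  stopifnot(group %in% model_groups, length(time_s) == length(rate_pre))
  structure(list(group = group, time_s = time_s, rate_pre = rate_pre,
                 rate_post = rate_pre * (1 + plasticity_strength),
                 plasticity_strength = plasticity_strength),
            class = "rate_template")
}

#' Build per-group rate templates from deconvolved single-neuron rates
#'
#' Within each direction group, each neuron's rate trace (response to
#' the temporo-nasal probe) is peak-normalized and the normalized traces
#' are averaged; all group averages are then rescaled by a common factor
#' so that their grand mean rate during the stimulation window matches
#' the supplied population mean rate, and the pre-onset baseline is
#' subtracted. Post-potentiation rates are the pre rates multiplied by
#' `1 + dR` of the corresponding group.
#'
#' @param rates Numeric matrix, time samples x neurons (deconvolved
#'   rates to the probe stimulus).
#' @param time_s Time grid (0 = stimulus onset; may include negative
#'   pre-onset times used for baseline subtraction).
#' @param groups Character vector, group of each neuron ("TN", "UP",
#'   "NT", "DN").
#' @param group_plasticity Named numeric vector of dR per group.
#' @param population_mean_rate Mean stimulation-window rate the scaled
#'   population should attain (spikes/s).
#' @param stim_window_s Window over which the mean rate is matched,
#'   default `c(0, max(time_s))`.
#' @return Named list of [rate_template()]s, one per group present.
#' @export
build_rate_templates <- function(rates, time_s, groups, group_plasticity,
                                 population_mean_rate = 1,
                                 stim_window_s = c(0, max(time_s))) {
  stopifnot(ncol(rates) == length(groups))
  present <- intersect(model_groups, unique(groups))
  if (length(setdiff(model_groups, present)))
    stop("empty direction group(s): ",
         paste(setdiff(model_groups, present), collapse = ", "))

  avg <- lapply(present, function(g) {
    m <- rates[, groups == g, drop = FALSE]
    peaks <- apply(m, 2L, max)
    keep <- peaks > 0
    if (!any(keep)) stop("group ", g, " has no active neurons")
    rowMeans(sweep(m[, keep, drop = FALSE], 2L, peaks[keep], "/"))
  })
  names(avg) <- present

  in_win <- time_s >= stim_window_s[1L] & time_s <= stim_window_s[2L]
  grand <- mean(vapply(avg, function(u) mean(u[in_win]), numeric(1)))
  scale <- population_mean_rate / grand

  out <- lapply(present, function(g) {
    u <- avg[[g]] * scale
    base <- if (any(time_s < 0)) mean(u[time_s < 0]) else 0
    rate_template(g, time_s, u - base,
                  unname(group_plasticity[[g]]))
  })
  names(out) <- present
  out
}

# largest-remainder apportionment of n among fractions
group_counts <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    order_rem <- order(raw - counts, decreasing = TRUE)
    counts[order_rem[seq_len(short)]] <- counts[order_rem[seq_len(short)]] + 1
  }
  counts
}

#' Simulate the feedforward synaptic current
#'
#' Integrates `tau dI/dt = -I + S(t)` with
#' `S(t) = sum_g count_g w u_g(t)`, where the group counts are the
#' largest-remainder rounding of `fraction x n_neurons`. The linear ODE
#' is advanced with the exact exponential update for piecewise-constant
#' input, `I[k+1] = I[k] e^{-dt/tau} + S[k] (1 - e^{-dt/tau})`, which
#' reproduces the analytic step response exactly. Charge is the
#' trapezoidal integral of the current over `[0, charge_window_s]`.
#'
#' @param templates Named list of [rate_template()]s (one per group).
#' @param composition Named fractions over the groups (sum to 1).
#' @param config A [model_config()].
#' @param phase "pre" or "post" (which rate of each template drives the
#'   model).
#' @return A `current_trace` list: `time_s`, `I_s`, `charge`,
#'   `group_counts`.
#' @export
simulate_current <- function(templates, composition, config = model_config(),
                             phase = c("pre", "post")) {
  phase <- match.arg(phase)
  gnames <- names(templates)
  if (is.null(names(composition))) names(composition) <- gnames
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  counts <- group_counts(composition[gnames], config$n_neurons)

  t <- seq(0, config$charge_window_s, by = config$dt_s)
  s_tot <- numeric(length(t))
  for (g in gnames) {
    tpl <- templates[[g]]
    u <- tpl[[if (phase == "pre") "rate_pre" else "rate_post"]]
    ug <- stats::approx(tpl$time_s, u, xout = t, rule = 2)$y
    s_tot <- s_tot + counts[[g]] * config$w * ug
  }

  e <- exp(-config$dt_s / config$tau_s)
  i_s <- numeric(length(t))
  for (k in seq_along(t)[-1L])
    i_s[k] <- i_s[k - 1L] * e + s_tot[k - 1L] * (1 - e)

  structure(
    list(time_s = t, I_s = i_s, charge = trapz(t, i_s),
         group_counts = counts),
    class = "current_trace")
}

trapz <- function(x, y) sum(diff(x) * (y[-1L] + y[-length(y)])) / 2

#' Fractional change in synaptic charge
#'
#' `dC = (C_post - C_pre) / C_pre`; multiplied by 100 when displayed as
#' a percentage.
#'
#' @param c_pre,c_post Charge before and after potentiation (`c_pre`
#'   must be > 0).
#' @return Dimensionless fractional change.
#' @export
delta_charge <- function(c_pre, c_post) {
  if (any(c_pre <= 0)) stop("c_pre must be > 0")
  (c_post - c_pre) / c_pre
}

#' Bundle templates, composition and plasticity for one population
#'
#' @param templates Named list of [rate_template()]s per group (their
#'   own plasticity strengths are overridden by `plasticity` when the
#'   bank is used in a scenario).
#' @param composition Named group fractions.
#' @param plasticity Named dR per group.
#' @return A `template_bank` list.
#' @export
template_bank <- function(templates, composition, plasticity) {
  stopifnot(!is.null(names(composition)), !is.null(names(plasticity)))
  structure(list(templates = templates, composition = composition,
                 plasticity = plasticity), class = "template_bank")
}

apply_plasticity <- function(templates, plasticity) {
  out <- lapply(names(templates), function(g)
    rate_template(g, templates[[g]]$time_s, templates[[g]]$rate_pre,
                  unname(plasticity[[g]])))
  names(out) <- names(templates)
  out
}

charge_change <- function(templates, composition, plasticity, config) {
  tpl <- apply_plasticity(templates, plasticity)
  pre <- simulate_current(tpl, composition, config, "pre")
  post <- simulate_current(tpl, composition, config, "post")
  list(c_pre = pre$charge, c_post = post$charge,
       delta_c = delta_charge(pre$charge, post$charge))
}

#' Run a perturbation scenario
#'
#' Assembles the model from named sources: the group composition and
#' response templates can each come from the NOT-DTN-projecting or the
#' midbrain-projecting bank (or custom fractions), and the plasticity
#' map can be the original differential map, a uniform map (every group
#' set to the mean of the four NOT-DTN group strengths), the NOT-DTN
#' map with the TN and NT strengths swapped, or the midbrain map. The
#' result is the fractional charge change of the assembled model.
#'
#' @param spec List with `composition_source` ("notdtn", "midbrain", or
#'   a named numeric vector of fractions), `response_source` ("notdtn"
#'   or "midbrain"), `plasticity_source` ("differential", "uniform",
#'   "swapped", or "midbrain").
#' @param banks List with elements `notdtn` and `midbrain`, each a
#'   [template_bank()].
#' @param config A [model_config()].
#' @return List with `c_pre`, `c_post`, `delta_c`.
#' @export
run_scenario <- function(spec, banks, config = model_config()) {
  comp <- if (is.numeric(spec$composition_source)) {
    spec$composition_source
  } else if (spec$composition_source %in% names(banks)) {
    banks[[spec$composition_source]]$composition
  } else stop("unresolvable composition_source")

  if (!spec$response_source %in% names(banks))
    stop("unresolvable response_source")
  templates <- banks[[spec$response_source]]$templates

  plast <- switch(spec$plasticity_source,
    differential = banks$notdtn$plasticity,
    uniform = {
      p <- banks$notdtn$plasticity
      stats::setNames(rep(mean(p), length(p)), names(p))
    },
    swapped = {
      p <- banks$notdtn$plasticity
      tmp <- p[["TN"]]; p[["TN"]] <- p[["NT"]]; p[["NT"]] <- tmp
      p
    },
    midbrain = banks$midbrain$plasticity,
    stop("unresolvable plasticity_source"))

  charge_change(templates, comp, plast, config)
}

#' Sweep the temporo-nasal fraction of the population
#'
#' At each grid point the TN group holds the stated fraction of the
#' model neurons and the remaining neurons are split among UP/NT/DN in
#' proportion to their fractions in the bank's composition. Returns the
#' fractional charge change at each point.
#'
#' @param fractions Numeric grid of TN fractions in [0, 1].
#' @param bank A [template_bank()] providing templates and the base
#'   composition.
#' @param config A [model_config()].
#' @param plasticity Optional plasticity map overriding the bank's.
#' @return Data frame `tn_fraction`, `delta_c`.
#' @export
sweep_tn_fraction <- function(fractions, bank, config = model_config(),
                              plasticity = bank$plasticity) {
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must lie in [0, 1]")
  base <- bank$composition
  others <- setdiff(names(base), "TN")
  rest <- base[others] / sum(base[others])
  dc <- vapply(fractions, function(f) {
    comp <- c(TN = f, rest * (1 - f))
    charge_change(bank$templates, comp[names(base)], plasticity,
                  config)$delta_c
  }, numeric(1))
  data.frame(tn_fraction = fractions, delta_c = dc)
}

#' Sweep the plasticity strength of the TN group
#'
#' Varies dR of the temporo-nasally biased group with everything else
#' fixed. Because the current equation is linear in the rates, the
#' resulting curve is affine in dR_TN with slope equal to the TN group's
#' share of the pre-potentiation charge.
#'
#' @param strengths Numeric grid of dR_TN values (> -1).
#' @param bank A [template_bank()].
#' @param config A [model_config()].
#' @return Data frame `tn_plasticity`, `delta_c`.
#' @export
sweep_tn_plasticity <- function(strengths, bank, config = model_config()) {
  if (any(strengths <= -1)) stop("strengths must be > -1")
  dc <- vapply(strengths, function(s) {
    p <- bank$plasticity
    p[["TN"]] <- s
    charge_change(bank$templates, bank$composition, p, config)$delta_c
  }, numeric(1))
  data.frame(tn_plasticity = strengths, delta_c = dc)
}
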