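# shared fixtures built in code

standard_drum <- function(...) drum_stimulus(...)

# four-group constant-rate templates for model analytics
flat_templates <- function(rates = c(TN = 1, UP = 1, NT = 1, DN = 1),
                           plasticity = c(TN = 0, UP = 0, NT = 0, DN = 0),
                           t_end = 3.5) {
  out <- lapply(names(rates), function(g)
    rate_template(g, c(0, t_end), rep(rates[[g]], 2), plasticity[[g]]))
  names(out) <- names(rates)
  out
}

even_composition <- c(TN = 0.25, UP = 0.25, NT = 0.25, DN = 0.25)

# independent LS oracle for OKR gain: regress the eye trace on
# sin/cos at the stimulus frequency plus a step regressor per true
# in-window saccade (ground truth)
ls_gain_oracle <- function(trace, stim) {
  gt <- attr(trace, "ground_truth")
  t <- trace$time_s
  f <- stim$oscillation_freq_hz
  in_win <- t >= stim$pre_s & t <= stim$pre_s + stim$duration_s
  X <- cbind(1, sin(2 * pi * f * (t - stim$pre_s)),
             cos(2 * pi * f * (t - stim$pre_s)))
  for (ts in gt$saccade_times_s)
    if (ts > stim$pre_s && ts < stim$pre_s + stim$duration_s)
      X <- cbind(X, as.numeric(t >= ts))
  beta <- stats::lm.fit(X[in_win, , drop = FALSE],
                        trace$position_deg[in_win])$coefficients
  sqrt(beta[2]^2 + beta[3]^2) / stim$amplitude_deg
}
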