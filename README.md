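# okrcircuit

Quantitative toolkit for studying how visual cortex drives the brainstem
circuit of the horizontal optokinetic reflex (OKR) — the involuntary eye
movement that stabilizes gaze during large-field visual motion. The
package covers the full analysis chain of a corticofugal-pathway study:
eye-movement gain, direction tuning of cortical and brainstem neurons,
response plasticity after prolonged OKR stimulation, population bias
statistics and cell-density maps, and a firing-rate model of the
synaptic drive that cortical populations deliver to the nucleus of the
optic tract / dorsal terminal nucleus (NOT-DTN). A synthetic-data module
generates every input with known ground truth, so each estimator can be
validated by parameter recovery without any recordings.

## What it computes

**OKR gain.** Eye-position traces (100 Hz video-oculography) tracking a
sinusoidally oscillating "virtual drum" grating are desaccaded —
velocity surges above threshold are interpolated in the velocity domain
and reintegrated, leaving only slow eye movements — and the gain is the
Fourier amplitude ratio at the oscillation frequency:

    gain = Amp_eye / Amp_drum

so a perfectly tracking eye gives 1 and a motionless eye gives 0.
Derived behavioral metrics: cortical contribution
ΔV(%) = 100·(V_control − V_silencing)/V_control (recordings with
V_control < 0.02 excluded), and OKR potentiation
(V_post − V_pre)/V_pre.

**Direction tuning.** Per-trial ΔF/F = (F_I − F_0)/F_0 with F_0 the mean
fluorescence over the 1 s before stimulation; Tukey-fence outlier-trial
removal (1.5×IQR); responsiveness gates (peak amplitude ≥ 6% ΔF/F and
two-sample t-test vs blank, p < 0.05); vector-sum preferred orientation
θ_pref = ½·arg Σ R·e^{2iρ} and direction ρ_pref = arg Σ R·e^{iρ};
DSI = (R_pref − R_null)/(|R_pref| + |R_null|); SF/TF selectivity
(R_pref − R_base)/(R_pref + R_base) with R_base the mean of the two
smallest amplitudes; nonnegative exponential-kernel deconvolution
(τ = 1.5 s, GCaMP6s); evoked rates, paired-t responsiveness (p < 0.01),
and antidromic latency/jitter from optogenetic tagging (3×SD PSTH onset
rule).

**Plasticity.** Per-neuron plasticity index
PI = (R_post − R_pre)/(R_post + R_pre) and strength
ΔR = (R_post − R_pre)/R_pre, grouped by preferred direction (TN/UP/NT/DN),
plus the two regression flavours (Gaussian-MLE least squares and
minimum-absolute-vertical-distance) relating behavioral potentiation to
cortical plasticity.

**Feedforward model.** Per-group firing-rate templates drive the leaky
synaptic-current equation

    τ dI_s/dt = −I_s + Σ_b w_b u_b

with τ = 3.9 ms (AMPA), uniform w = 0.005, N = 100 neurons; charge is
the integral of I_s over 3.5 s from stimulus onset, and
ΔC = (C_post − C_pre)/C_pre quantifies the extra cortical drive created
by plasticity. Scenario machinery swaps composition, response and
plasticity sources between NOT-DTN-projecting and midbrain-projecting
banks, and sweeps the TN fraction and TN plasticity strength.

**Population statistics.** One-sided randomization test for
direction-preference bias (uniform multinomial null, focal-bin count
statistic, exact binomial tail as reference), volumetric densities, and
100 µm × 100 µm density grids with per-square density ratios.

## Worked example

```r
library(okrcircuit)

stim <- drum_stimulus(amplitude_deg = 5, oscillation_freq_hz = 0.4,
                      duration_s = 10)
trace <- gen_eye_trace(stim, eye_spec(true_gain = 0.6,
                                      saccade_rate_hz = 0.2,
                                      noise_sd_deg = 0.05), seed = 1)
okr_gain(trace)
#> <gain_result> gain = 0.6090 (Amp_eye 3.045 deg / Amp_drum 5.000 deg, 4 cycles, 0.7% samples interpolated)
```

The synthetic eye tracked the 5-degree drum with a generative gain of
0.6 while making saccades; after desaccading, the Fourier amplitude
ratio recovers 0.609.

```r
banks <- list(notdtn = synthetic_bank("notdtn", seed = 10),
              midbrain = synthetic_bank("midbrain", seed = 20))
run_scenario(list(composition_source = "notdtn",
                  response_source = "notdtn",
                  plasticity_source = "differential"), banks)$delta_c
#> [1] 0.6387392
run_scenario(list(composition_source = "midbrain",
                  response_source = "midbrain",
                  plasticity_source = "midbrain"), banks)$delta_c
#> [1] 0.4467136
```

Upon plasticity the temporo-nasally enriched, strongly
direction-selective population boosts its drive onto the NOT-DTN by 64%
versus 45% for the flat midbrain-projecting population — the
NOT-DTN-projecting population converts the same induction into more
extra charge.

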