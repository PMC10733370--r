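test_that("drum trajectory follows the sinusoid and sample count rule", {
  stim <- drum_stimulus(amplitude_deg = 5, oscillation_freq_hz = 0.4,
                        duration_s = 10, pre_s = 1, post_s = 1)
  tr <- gen_drum_trajectory(stim, sampling_rate_hz = 100)

  expect_equal(nrow(tr), round(12 * 100) + 1)
  # sine peak at a quarter period into the stimulation window
  expect_equal(drum_position(stim, 1 + 0.625), 5)
  expect_equal(tr$position_deg[tr$time_s == 0], 0)
  # exactly 4 full cycles: position returns to 0 at stimulation offset
  expect_equal(tr$position_deg[tr$time_s == 11], 0, tolerance = 1e-12)
  # padding is stationary
  expect_true(all(tr$position_deg[tr$time_s < 1 | tr$time_s > 11] == 0))

  expect_error(gen_drum_trajectory(stim, sampling_rate_hz = 0),
               "sampling_rate_hz")
  expect_error(drum_stimulus(duration_s = -1), "duration_s")
  expect_error(drum_stimulus(amplitude_deg = 0), "amplitude_deg")
})

test_that("unidirectional drum ramps at tf/sf degrees per second", {
  stim <- drum_stimulus("unidirectional", oscillation_freq_hz = 0.4,
                        sf_cpd = 0.1, duration_s = 10, direction_deg = 0)
  tr <- gen_drum_trajectory(stim, 100)
  # 0.4 Hz / 0.1 cpd = 4 deg/s along temporo-nasal (positive)
  expect_equal(tr$position_deg[tr$time_s == 6], 4 * 5)
  stim180 <- drum_stimulus("unidirectional", oscillation_freq_hz = 0.4,
                           sf_cpd = 0.1, duration_s = 10,
                           direction_deg = 180)
  tr180 <- gen_drum_trajectory(stim180, 100)
  expect_equal(tr180$position_deg, -tr$position_deg)
})

test_that("eye-trace generator reduces to the drum and is deterministic", {
  stim <- standard_drum()
  tr <- gen_eye_trace(stim, eye_spec(true_gain = 1), seed = 3)
  drum <- gen_drum_trajectory(stim, 100)
  expect_equal(tr$position_deg, drum$position_deg)

  tr0 <- gen_eye_trace(stim, eye_spec(true_gain = 0), seed = 3)
  expect_true(all(tr0$position_deg == 0))

  a <- gen_eye_trace(stim, eye_spec(0.5, 0.02, 0.3, 8, 0.01, 0.05),
                     seed = 7)
  b <- gen_eye_trace(stim, eye_spec(0.5, 0.02, 0.3, 8, 0.01, 0.05),
                     seed = 7)
  expect_identical(a$position_deg, b$position_deg)
  c_ <- gen_eye_trace(stim, eye_spec(0.5, 0.02, 0.3, 8, 0.01, 0.05),
                      seed = 8)
  expect_false(identical(a$position_deg, c_$position_deg))
})

test_that("noisy saccadic traces recover the generative gain (LS oracle)", {
  stim <- standard_drum()
  est <- oracle <- numeric(20)
  for (s in 1:20) {
    tr <- gen_eye_trace(stim, eye_spec(0.6, 0, 0.2, 8, 0, 0.05),
                        seed = 100 + s)
    est[s] <- okr_gain(tr)$gain
    oracle[s] <- ls_gain_oracle(tr, stim)
  }
  expect_lt(abs(mean(est) - 0.6), 0.02)
  expect_lt(abs(mean(oracle) - 0.6), 0.02)
  expect_lt(max(abs(est - oracle)), 0.05)
})

test_that("calcium generator has multiplicative plasticity and clean nulls", {
  ns <- neuron_spec(0, tuning_width_deg = 25, peak_amp = 0.3,
                    dir_null_ratio = 0, plasticity_factor = 1.5)
  pre <- gen_calcium_trials(list(ns), n_trials = 3, noise_sd = 0, seed = 1)
  post <- gen_calcium_trials(list(ns), n_trials = 3, noise_sd = 0,
                             seed = 1, phase = "post")
  cu_pre <- tuning_curves(pre)
  cu_post <- tuning_curves(post)
  # null direction response vanishes (tiny von Mises cross-lobe tail)
  expect_lt(abs(cu_pre$R[cu_pre$direction_deg %in% 180]), 1e-4)
  # post/pre ratio equals the plasticity factor at every direction
  act <- !is.na(cu_pre$direction_deg) & cu_pre$R > 1e-12
  expect_equal(cu_post$R[act] / cu_pre$R[act],
               rep(1.5, sum(act)), tolerance = 1e-9)
  expect_error(gen_calcium_trials(list(), seed = 1), "empty")
})

test_that("preferred directions are recovered within one 45-degree bin", {
  dirs <- seq(0, 315, by = 45)
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    pop <- sample_population(
      20, setNames(rep(1 / 8, 8), dirs), dir_null_ratio = 0.4,
      jitter_deg = 20, seed = s)
    trials <- gen_calcium_trials(pop, dirs, n_trials = 2, noise_sd = 0,
                                 seed = s, blank_trials = 0)
    cu <- tuning_curves(trials)
    for (id in unique(cu$neuron_id)) {
      cv <- cu[cu$neuron_id == id & !is.na(cu$direction_deg), ]
      pd <- preferred_direction(cv$R, cv$direction_deg)
      truth <- pop[[id]]$pref_direction_deg
      total <- total + 1L
      if (min(abs(pd$sampled_pref_deg - truth) %% 360,
              360 - abs(pd$sampled_pref_deg - truth) %% 360) <= 45 / 2 + 1e-9)
        hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("spike generator respects rates and antidromic structure", {
  u0 <- gen_spike_unit(0, 0, 0, n_trials = 3, seed = 1)
  expect_equal(nrow(u0$spikes), 0)

  ua <- gen_spike_unit(0, 0, 0, n_trials = 2, seed = 2,
                       antidromic = list(latency_ms = 5, jitter_ms = 0,
                                         n_pulses = 40))
  rel <- ua$antidromic$spike_times_s - ua$antidromic$pulse_times_s
  expect_equal(rel, rep(5e-3, 40), tolerance = 1e-12)

  # sample statistics of generated antidromic spikes match the request
  ub <- gen_spike_unit(0, 0, 0, n_trials = 2, seed = 3,
                       antidromic = list(latency_ms = 5.5,
                                         jitter_ms = 0.4,
                                         n_pulses = 200))
  relb <- (ub$antidromic$spike_times_s - ub$antidromic$pulse_times_s) * 1e3
  expect_lt(abs(mean(relb) - 5.5), 0.5)
  expect_lt(abs(sd(relb) - 0.4), 0.1)
})

test_that("cell maps realize per-area Poisson intensities", {
  sq <- function(x0, y0, w) data.frame(
    x_um = c(x0, x0 + w, x0 + w, x0), y_um = c(y0, y0, y0 + w, y0 + w))
  polys <- list(A = sq(0, 0, 500), B = sq(600, 0, 500))

  empty <- gen_cell_map(polys, c(A = 0, B = 0), seed = 1)
  expect_equal(nrow(empty), 0)

  # density ratio 2:1 recovered over seeds
  ratios <- sapply(1:50, function(s) {
    m <- gen_cell_map(polys, c(A = 4e-4, B = 2e-4), seed = s)
    sum(m$area == "A") / sum(m$area == "B")
  })
  expect_lt(abs(mean(ratios) - 2), 0.2)

  # expected count equals density * area
  ns <- sapply(1:50, function(s)
    nrow(gen_cell_map(polys["A"], c(A = 4e-4), seed = 100 + s)))
  expect_lt(abs(mean(ns) - 4e-4 * 500^2), 3 * sqrt(4e-4 * 500^2 / 50))

  expect_error(
    gen_cell_map(list(Z = data.frame(x_um = c(0, 1, 2),
                                     y_um = c(0, 0, 0))),
                 c(Z = 1), seed = 1),
    "zero-area")
})
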