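test_that("the exponential update reproduces the analytic step response", {
  cfg <- model_config()
  tpl <- flat_templates()
  cur <- simulate_current(tpl, even_composition, cfg)
  W <- cfg$n_neurons * cfg$w
  analytic <- W * (1 - exp(-cur$time_s / cfg$tau_s))
  expect_lt(max(abs(cur$I_s - analytic)) / W, 1e-8)
  # steady state and positivity
  expect_equal(cur$I_s[length(cur$I_s)], W, tolerance = 1e-8)
  expect_true(all(cur$I_s >= 0))

  zero <- simulate_current(flat_templates(c(TN = 0, UP = 0, NT = 0,
                                            DN = 0)),
                           even_composition, cfg)
  expect_true(all(zero$I_s == 0))
  expect_equal(zero$charge, 0)

  expect_error(model_config(dt_s = 0.002), "dt_s")
})

test_that("charge matches an independent stiff-ODE oracle", {
  skip_if_not_installed("deSolve")
  cfg <- model_config()
  # time-varying input: ramping rates, different per group
  tgrid <- seq(0, 3.5, by = 0.01)
  tpl <- lapply(c(TN = 1, UP = 2, NT = 0.5, DN = 1.5), function(a)
    NULL)
  tpl <- list(
    TN = rate_template("TN", tgrid, pmin(tgrid, 1) * 10),
    UP = rate_template("UP", tgrid, sin(tgrid)^2 * 5),
    NT = rate_template("NT", tgrid, rep(2, length(tgrid))),
    DN = rate_template("DN", tgrid, exp(-tgrid) * 8))
  comp <- c(TN = 0.4, UP = 0.2, NT = 0.2, DN = 0.2)
  cur <- simulate_current(tpl, comp, cfg)

  counts <- cur$group_counts
  s_fun <- function(t) {
    s <- 0
    for (g in names(tpl))
      s <- s + counts[[g]] * cfg$w *
        approx(tpl[[g]]$time_s, tpl[[g]]$rate_pre, t, rule = 2)$y
    s
  }
  rhs <- function(t, y, parms)
    list((-y + s_fun(t)) / cfg$tau_s)
  sol <- deSolve::lsoda(0, cur$time_s, rhs, NULL, rtol = 1e-10,
                        atol = 1e-12)
  charge_ref <- sum(diff(cur$time_s) *
                      (sol[-1, 2] + sol[-nrow(sol), 2])) / 2
  expect_lt(abs(cur$charge - charge_ref) / charge_ref, 1e-4)
})

test_that("delta charge is the fractional change and linear identities hold", {
  expect_equal(delta_charge(100, 100), 0)
  expect_equal(delta_charge(100, 150), 0.5)
  expect_error(delta_charge(0, 1), "c_pre")

  cfg <- model_config()
  # uniform plasticity of strength r gives dC = r to machine precision
  for (r in c(0.2, 0.5, 1.1)) {
    tpl <- flat_templates(plasticity = c(TN = r, UP = r, NT = r, DN = r))
    pre <- simulate_current(tpl, even_composition, cfg, "pre")
    post <- simulate_current(tpl, even_composition, cfg, "post")
    expect_equal(delta_charge(pre$charge, post$charge), r,
                 tolerance = 1e-12)
  }
})

test_that("dC vs TN plasticity is affine with slope = TN charge share", {
  cfg <- model_config()
  tpl <- flat_templates(rates = c(TN = 3, UP = 1, NT = 0.5, DN = 1))
  bank <- template_bank(tpl, c(TN = 0.4, UP = 0.2, NT = 0.2, DN = 0.2),
                        c(TN = 0.8, UP = 0, NT = 0.1, DN = 0))
  grid <- seq(-0.5, 1.5, by = 0.25)
  sw <- sweep_tn_plasticity(grid, bank, cfg)
  fit <- lm(delta_c ~ tn_plasticity, sw)
  expect_lt(max(abs(resid(fit))), 1e-10)

  # slope equals the TN group's share of pre-potentiation charge
  all0 <- lapply(names(tpl), function(g)
    rate_template(g, tpl[[g]]$time_s, tpl[[g]]$rate_pre, 0))
  names(all0) <- names(tpl)
  pre_all <- simulate_current(all0, bank$composition, cfg, "pre")
  tn_only <- lapply(names(tpl), function(g)
    rate_template(g, tpl[[g]]$time_s,
                  if (g == "TN") tpl[[g]]$rate_pre else
                    rep(0, length(tpl[[g]]$rate_pre)), 0))
  names(tn_only) <- names(tpl)
  pre_tn <- simulate_current(tn_only, bank$composition, cfg, "pre")
  share <- pre_tn$charge / pre_all$charge
  expect_equal(unname(coef(fit)[2]), share, tolerance = 1e-9)
})

test_that("dC is invariant to the weight and to common rate rescaling", {
  tpl <- flat_templates(rates = c(TN = 3, UP = 1, NT = 0.5, DN = 1),
                        plasticity = c(TN = 0.8, UP = 0, NT = 0.1,
                                       DN = -0.1))
  comp <- c(TN = 0.4, UP = 0.2, NT = 0.2, DN = 0.2)
  dc <- function(cfg, scale = 1) {
    tpl2 <- lapply(names(tpl), function(g)
      rate_template(g, tpl[[g]]$time_s, tpl[[g]]$rate_pre * scale,
                    tpl[[g]]$plasticity_strength))
    names(tpl2) <- names(tpl)
    pre <- simulate_current(tpl2, comp, cfg, "pre")
    post <- simulate_current(tpl2, comp, cfg, "post")
    delta_charge(pre$charge, post$charge)
  }
  base <- dc(model_config())
  expect_equal(dc(model_config(w = 0.05)), base, tolerance = 1e-12)
  expect_equal(dc(model_config(), scale = 7), base, tolerance = 1e-12)
})

test_that("the tau -> 0 limit integrates the raw input", {
  cfg0 <- model_config(tau_s = 1e-6, dt_s = 2e-7,
                       charge_window_s = 0.05)
  tgrid <- seq(0, 0.05, by = 1e-4)
  tpl <- list(TN = rate_template("TN", tgrid, 5 + 3 * sin(50 * tgrid)),
              UP = rate_template("UP", tgrid, rep(1, length(tgrid))),
              NT = rate_template("NT", tgrid, rep(1, length(tgrid))),
              DN = rate_template("DN", tgrid, rep(1, length(tgrid))))
  cur <- simulate_current(tpl, even_composition, cfg0)
  counts <- cur$group_counts
  s <- rep(0, length(cur$time_s))
  for (g in names(tpl))
    s <- s + counts[[g]] * cfg0$w *
      approx(tgrid, tpl[[g]]$rate_pre, cur$time_s, rule = 2)$y
  ref <- sum(diff(cur$time_s) * (s[-1] + s[-length(s)])) / 2
  expect_lt(abs(cur$charge - ref) / ref, 1e-4)
})

test_that("scenario sources assemble composition, responses, plasticity", {
  tpl <- flat_templates(rates = c(TN = 3, UP = 1, NT = 0.5, DN = 1))
  tpl_weak <- flat_templates(rates = c(TN = 1.5, UP = 1, NT = 1, DN = 1))
  banks <- list(
    notdtn = template_bank(tpl, c(TN = 0.4, UP = 0.2, NT = 0.18,
                                  DN = 0.22),
                           c(TN = 0.8, UP = -0.1, NT = 0.15, DN = -0.1)),
    midbrain = template_bank(tpl_weak,
                             c(TN = 0.26, UP = 0.25, NT = 0.24,
                               DN = 0.25),
                             c(TN = 0.45, UP = 0.35, NT = 0.44,
                               DN = 0.35)))
  cfg <- model_config()
  dc_not <- run_scenario(list(composition_source = "notdtn",
                              response_source = "notdtn",
                              plasticity_source = "differential"),
                         banks, cfg)$delta_c
  dc_mid <- run_scenario(list(composition_source = "midbrain",
                              response_source = "midbrain",
                              plasticity_source = "midbrain"),
                         banks, cfg)$delta_c
  expect_gt(dc_not, dc_mid)

  # uniform plasticity: dC equals the mean strength, any composition
  dc_unif <- run_scenario(list(composition_source = "midbrain",
                               response_source = "notdtn",
                               plasticity_source = "uniform"),
                          banks, cfg)$delta_c
  expect_equal(dc_unif, mean(banks$notdtn$plasticity), tolerance = 1e-12)

  # swapping TN and NT changes dC by (dR_TN - dR_NT)(share_TN - share_NT)
  dc_swap <- run_scenario(list(composition_source = "notdtn",
                               response_source = "notdtn",
                               plasticity_source = "swapped"),
                          banks, cfg)$delta_c
  share <- function(g) {
    only <- lapply(names(tpl), function(h)
      rate_template(h, tpl[[h]]$time_s,
                    if (h == g) tpl[[h]]$rate_pre else
                      rep(0, length(tpl[[h]]$rate_pre)), 0))
    names(only) <- names(tpl)
    all0 <- lapply(names(tpl), function(h)
      rate_template(h, tpl[[h]]$time_s, tpl[[h]]$rate_pre, 0))
    names(all0) <- names(tpl)
    simulate_current(only, banks$notdtn$composition, cfg)$charge /
      simulate_current(all0, banks$notdtn$composition, cfg)$charge
  }
  p <- banks$notdtn$plasticity
  expected_shift <- (p[["TN"]] - p[["NT"]]) * (share("TN") - share("NT"))
  expect_equal(dc_not - dc_swap, expected_shift, tolerance = 1e-9)

  expect_error(run_scenario(list(composition_source = "nope",
                                 response_source = "notdtn",
                                 plasticity_source = "uniform"),
                            banks, cfg),
               "composition_source")
})

test_that("TN-fraction sweeps are flat under uniform, rising under TN-dominant plasticity", {
  cfg <- model_config()
  tpl <- flat_templates(rates = c(TN = 3, UP = 1, NT = 0.5, DN = 1))
  bank <- template_bank(tpl, c(TN = 0.4, UP = 0.2, NT = 0.2, DN = 0.2),
                        c(TN = 0.8, UP = -0.1, NT = 0.15, DN = -0.1))
  grid <- seq(0, 1, by = 0.1)

  unif <- sweep_tn_fraction(grid, bank, cfg,
                            plasticity = c(TN = 0.3, UP = 0.3, NT = 0.3,
                                           DN = 0.3))
  expect_lt(diff(range(unif$delta_c)), 1e-12)

  sw <- sweep_tn_fraction(grid, bank, cfg)
  expect_true(all(diff(sw$delta_c) > 0))
  # fraction 1: the whole population carries TN plasticity
  expect_equal(sw$delta_c[grid == 1], 0.8, tolerance = 1e-12)
})

test_that("group counts use largest-remainder rounding", {
  tpl <- flat_templates()
  cur <- simulate_current(tpl, c(TN = 0.27, UP = 0.26, NT = 0.24,
                                 DN = 0.23),
                          model_config(n_neurons = 10))
  expect_equal(sum(cur$group_counts), 10)
  expect_equal(unname(cur$group_counts), c(3, 3, 2, 2))
})

test_that("templates built from generator output recover group plasticity", {
  bank <- synthetic_bank("notdtn", n_neurons = 40, n_trials = 6,
                         noise_sd = 0.01, seed = 5)
  truth <- notdtn_plasticity()
  for (g in names(bank$templates)) {
    tpl <- bank$templates[[g]]
    # multiplicative construction: implied strength matches the map
    expect_equal(tpl$plasticity_strength, unname(truth[[g]]),
                 tolerance = 1e-12)
    active <- abs(tpl$rate_pre) > 1e-9
    expect_equal(tpl$rate_post[active] / tpl$rate_pre[active],
                 rep(1 + truth[[g]], sum(active)), tolerance = 1e-9)
    # pre-onset baseline subtracted
    expect_lt(abs(mean(tpl$rate_pre[tpl$time_s < 0])), 1e-9)
  }
})
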