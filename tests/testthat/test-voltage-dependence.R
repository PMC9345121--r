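test_that("peak measurement subtracts baseline and preserves sign", {
  flat <- data.frame(time = seq(0, 100, 0.1), command = -90, current = 0)
  expect_equal(peak_current(flat, window = c(10, 90))$i_peak, 0)

  p <- toy_params()
  seg <- data.frame(duration = c(10, 100, 10), voltage = c(-90, -10, -90))
  sw <- simulate_sweep(seg, p, noise_sd = 0)
  pm <- peak_current(sw, window = c(10, 110), smooth_ms = 0)
  expect_lt(pm$i_peak, 0)
  expect_gte(pm$peak_time, 10)
  expect_lte(pm$peak_time, 110)

  # baseline offset invariance
  sw2 <- sw
  sw2$current <- sw$current + 50
  pm2 <- peak_current(sw2, window = c(10, 110), smooth_ms = 0)
  expect_equal(pm2$i_peak, pm$i_peak, tolerance = 1e-9)
  expect_equal(pm2$baseline, pm$baseline + 50, tolerance = 1e-9)

  expect_error(peak_current(sw, window = c(200, 300)), "window")
})

test_that("current density divides peak magnitude by capacitance", {
  p <- toy_params()
  rec <- simulate_recording(p, protocol_density(), capacitance = 10,
                            noise_sd = 0)
  pm <- peak_current(rec$sweeps[[1]], window = c(10, 110), smooth_ms = 0)
  d <- current_density(rec)
  expect_equal(d$density, abs(pm$i_peak) / 10, tolerance = 1e-4)
  expect_gte(d$density, 0)

  # zero-conductance cell has zero density
  rec0 <- simulate_recording(toy_params(gmax = 0), protocol_density(),
                             capacitance = 10, noise_sd = 0)
  expect_equal(current_density(rec0)$density, 0)

  rec$capacitance <- -1
  expect_error(current_density(rec), "capacitance")
})

test_that("WT-like cohort density lands on the configured target", {
  fx <- cav33_fixtures()
  recs <- generate_cohort(fx$WT, protocol_density(), n_cells = 17,
                          seed = 2026)
  d <- analyze_density(recs)
  sem <- stats::sd(d$density) / sqrt(nrow(d))
  expect_lt(abs(mean(d$density) - 208.4), 2 * sem)
})

test_that("normalized G-V and availability curves behave as curves", {
  p <- toy_params()
  rec <- simulate_recording(p, protocol_iv(), noise_sd = 0)
  gv <- build_gv(rec)
  expect_equal(max(gv$value), 1)
  # exclusion band around erev (+45): no voltages in [40, 50]
  expect_false(any(abs(gv$voltage - p$erev) <= 5))
  # normalization invariance: scaling all currents leaves the curve fixed
  rec2 <- rec
  rec2$sweeps <- lapply(rec$sweeps, function(sw) {
    sw$current <- 2 * sw$current
    sw
  })
  expect_equal(build_gv(rec2)$value, gv$value, tolerance = 1e-12)

  # the normalized G-V tracks m_inf at depolarized voltages (constant
  # transient correction)
  m <- steady_state_activation(gv$voltage, p)
  sel <- gv$voltage >= -10 & gv$voltage <= 30
  expect_equal(gv$value[sel], (m / max(m))[sel], tolerance = 2e-2)

  av <- build_availability(simulate_recording(p, protocol_ssi(),
                                              noise_sd = 0))
  expect_equal(max(av$value), 1)
  expect_equal(av$value[av$voltage == -90], 1)        # fully available
  expect_lt(av$value[av$voltage == 20], 0.05)         # fully inactivated
  # a 1-s prepulse (>> tau_inact) drives h to steady state, so the curve
  # interpolates to one half at the half-inactivation voltage
  at_v05 <- stats::approx(av$voltage, av$value, xout = p$inact_v05)$y
  expect_equal(at_v05, 0.5, tolerance = 0.05)
})

test_that("noiseless recordings round-trip to the generating parameters", {
  # zero noise, zero cell variability: fitted parameters track the
  # generating ones up to the model's measurement artifacts (transient
  # correction of the G-V curve; availability floor from re-equilibration
  # toward h_inf(-20 mV) during the SSI test pulse, largest for shallow,
  # slowly inactivating constructs)
  fx <- cav33_fixtures()
  for (cs in c("WT", "M128L", "Q1158H")) {
    p <- fx[[cs]]
    fa <- fit_boltzmann(build_gv(simulate_recording(p, protocol_iv(),
                                                    noise_sd = 0)),
                        "activation")
    expect_true(fa$converged)
    expect_lt(abs(fa$v05 - p$act_v05), 0.25)
    expect_lt(abs(fa$slope - p$act_slope), 0.1)

    fi <- fit_boltzmann(build_availability(
      simulate_recording(p, protocol_ssi(), noise_sd = 0)), "inactivation")
    expect_true(fi$converged)
    expect_lt(abs(fi$v05 - p$inact_v05), 0.7)
    expect_lt(abs(fi$slope - p$inact_slope), 0.6)
  }
})

test_that("Boltzmann fitting recovers generating parameters and honors contracts", {
  v <- seq(-90, 10, by = 5)
  exact <- data.frame(voltage = v,
                      value = 1 / (1 + exp((-20.6 - v) / 5.8)))
  f <- fit_boltzmann(exact, "activation")
  expect_true(f$converged)
  expect_equal(f$v05, -20.6, tolerance = 1e-6)
  expect_equal(f$slope, 5.8, tolerance = 1e-6)

  # property: noiseless recovery across random parameters, slope 2..15 mV
  set.seed(7)
  for (i in 1:20) {
    v05 <- runif(1, -60, -10)
    k <- runif(1, 2, 15)
    orient <- sample(c("activation", "inactivation"), 1)
    val <- if (orient == "activation") 1 / (1 + exp((v05 - v) / k))
           else 1 / (1 + exp((v - v05) / k))
    fr <- fit_boltzmann(data.frame(voltage = v, value = val), orient)
    expect_true(fr$converged)
    expect_equal(fr$v05, v05, tolerance = 1e-4)
    expect_equal(fr$slope, k, tolerance = 1e-4)
  }

  # equivariance: shifting all voltages by delta shifts v05, not slope
  delta <- 13.5
  f2 <- fit_boltzmann(data.frame(voltage = v + delta, value = exact$value),
                      "activation")
  expect_equal(f2$v05, f$v05 + delta, tolerance = 1e-6)
  expect_equal(f2$slope, f$slope, tolerance = 1e-6)

  # contracts
  expect_error(fit_boltzmann(exact[1:4, ], "activation"), "5 points")
  flat <- data.frame(voltage = v, value = rep(0.7, length(v)))
  expect_false(fit_boltzmann(flat, "activation")$converged)
  # wrong orientation for the trend -> not converged, no exception
  expect_false(fit_boltzmann(exact, "inactivation")$converged)
})
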