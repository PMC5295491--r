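test_that("Bramwell-Hill wave speed matches hand unit conversion", {
  # sqrt(5 * 40 * 133.322 / (1060 * 1)) = 5.0155 m/s
  expect_equal(bramwell_hill_pwv(5, 1, 40), sqrt(5 * 40 * 133.322 / 1060),
               tolerance = 1e-12)
  expect_equal(bramwell_hill_pwv(5, 1, 40), 5.02, tolerance = 0.01)
  # quadrupling the pulse pressure doubles the speed
  expect_equal(bramwell_hill_pwv(5, 1, 160), 2 * bramwell_hill_pwv(5, 1, 40),
               tolerance = 1e-12)
  # large distension drives the speed to zero
  expect_lt(bramwell_hill_pwv(5, 1e6, 40), 1e-2)
  expect_error(bramwell_hill_pwv(5, 0, 40), class = "coawave_error_pwv")
})

test_that("characteristic impedance converts rho*c/A to mmHg s/mL", {
  zc <- characteristic_impedance(5, 5)
  expect_equal(zc, 1060 * 5 / 5e-4 / 133.322 / 1e6, tolerance = 1e-12)
  expect_equal(zc, 0.0795, tolerance = 1e-3)
  expect_equal(characteristic_impedance(5, 10), zc / 2, tolerance = 1e-12)
  # identity zc * A / c = rho in SI, for arbitrary inputs
  for (c_ms in c(3, 5, 9)) {
    for (a in c(3, 5, 8)) {
      z_si <- characteristic_impedance(c_ms, a) * 133.322 * 1e6
      expect_equal(z_si * (a * 1e-4) / c_ms, 1060, tolerance = 1e-9)
    }
  }
})

test_that("stroke volume and cardiac output integrate the flow curve", {
  n <- 100
  t <- (seq_len(n) - 1) * 0.01               # period exactly 1 s
  flow <- ifelse(t < 0.3, 300, 0)            # 300 mL/s for 0.3 s
  cyc <- aortic_cycle(tibble::tibble(time = t, area = rep(5, n), flow = flow))
  co <- cardiac_output(cyc)
  expect_equal(co$stroke_volume, 90, tolerance = 1e-9)
  expect_equal(co$cardiac_output, 5.4, tolerance = 1e-9)

  # halving the period doubles CO at fixed SV
  t2 <- (seq_len(50) - 1) * 0.01
  cyc2 <- aortic_cycle(tibble::tibble(time = t2, area = rep(5, 50),
                                      flow = ifelse(t2 < 0.3, 300, 0)))
  expect_equal(cardiac_output(cyc2)$cardiac_output, 10.8, tolerance = 1e-9)

  zero <- aortic_cycle(tibble::tibble(time = t, area = rep(5, n),
                                      flow = rep(0, n)))
  expect_warning(co0 <- cardiac_output(zero), "zero stroke volume")
  expect_equal(co0$stroke_volume, 0)
  neg <- aortic_cycle(tibble::tibble(time = t, area = rep(5, n),
                                     flow = -flow))
  expect_error(cardiac_output(neg), class = "coawave_error_flow_sign")
})

test_that("arterial resistance divides mean pressure by cardiac output", {
  r <- arterial_resistance(90, 5, bsa = 2)
  expect_equal(r$resistance, 18)
  expect_equal(r$resistance_indexed, 36)
  expect_error(arterial_resistance(90, 0), class = "coawave_error_resistance")
})

test_that("windkessel pulse pressure is monotone in C and R", {
  cyc <- make_cycle()
  cs <- c(0.3, 0.6, 1.2, 2.4, 4.8)
  pps <- vapply(cs, function(cc) {
    p <- windkessel_pressure(cyc, 18, cc)$pressure
    max(p) - min(p)
  }, numeric(1))
  expect_true(all(diff(pps) < 0))
  rs <- c(5, 10, 20, 40)
  ppr <- vapply(rs, function(r) {
    p <- windkessel_pressure(cyc, r, 1.2)$pressure
    max(p) - min(p)
  }, numeric(1))
  expect_true(all(diff(ppr) > 0))
})

test_that("closed-form periodic windkessel agrees with an RK4 time-stepper", {
  set.seed(5)
  for (i in 1:6) {
    cyc <- make_cycle(q_peak = runif(1, 250, 500))
    r <- runif(1, 10, 25)
    cc <- runif(1, 0.5, 3)
    p <- windkessel_pressure(cyc, r, cc)$pressure
    pp_closed <- max(p) - min(p)
    pp_oracle <- wk_pp_ode(cyc, r, cc)
    expect_equal(pp_closed, pp_oracle, tolerance = 5e-3)
  }
})

test_that("TAC tuning recovers the compliance that generated the pulse pressure", {
  set.seed(9)
  for (i in 1:5) {
    cyc <- make_cycle(q_peak = runif(1, 250, 500))
    r <- runif(1, 12, 22)
    c_true <- runif(1, 0.6, 2.5)
    p <- windkessel_pressure(cyc, r, c_true)$pressure
    c_hat <- tac_windkessel(cyc, r, max(p) - min(p))
    expect_equal(c_hat, c_true, tolerance = 0.01 * c_true)
  }
  flat <- aortic_cycle(tibble::tibble(time = (0:29) * 0.01,
                                      area = rep(5, 30), flow = rep(80, 30)))
  expect_error(tac_windkessel(flat, 18, 40),
               class = "coawave_error_pp_unreachable")
})

test_that("central TAC exceeds brachial TAC whenever central PP is lower", {
  cyc <- make_cycle()
  tac_c <- tac_windkessel(cyc, 18, 35)   # central pulse pressure
  tac_b <- tac_windkessel(cyc, 18, 45)   # larger brachial pulse pressure
  expect_gt(tac_c, tac_b)
})

test_that("morphology indices and the recoarctation flag", {
  m <- morphology_indices(20.8, 18.2, 20.0)
  expect_equal(m$ci, 0.91, tolerance = 1e-12)
  expect_equal(m$ti, 1.04, tolerance = 1e-12)
  expect_false(m$recoarctation_suspected)

  eq <- morphology_indices(20, 20, 20)
  expect_equal(eq$ti, 1)
  expect_equal(eq$ci, 1)

  flag <- morphology_indices(20, 13.8, 20)
  expect_equal(flag$ci, 0.69)
  expect_true(flag$recoarctation_suspected)

  missing <- morphology_indices(NA, NA, 20)
  expect_true(is.na(missing$ti) && is.na(missing$ci))
  expect_error(morphology_indices(-1, 18, 20), class = "coawave_error_diameter")
})
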