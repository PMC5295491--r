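random_increments <- function(n = 60) {
  tibble::tibble(
    t_mid = (seq_len(n) - 0.5) * 0.0096,
    dA = rnorm(n, 0, 0.05),
    dQ = rnorm(n, 0, 20)
  )
}

test_that("wave separation satisfies its algebraic identities on random input", {
  set.seed(1)
  for (i in 1:50) {
    inc <- random_increments()
    pwv <- runif(1, 2, 10)
    sep <- separate_waves(inc, pwv)
    scale_A <- max(abs(sep$dA))
    scale_Q <- max(abs(sep$dQ))
    scale_I <- max(abs(sep$dI))
    expect_lt(max(abs(sep$dA_plus + sep$dA_minus - sep$dA)), 1e-12 * scale_A)
    expect_lt(max(abs(sep$dQ_plus + sep$dQ_minus - sep$dQ)), 1e-12 * scale_Q)
    expect_lt(max(abs(sep$dI_plus + sep$dI_minus - sep$dI)), 1e-12 * scale_I)
    expect_true(all(sep$dI_plus >= 0))
    expect_true(all(sep$dI_minus <= 0))
  }
})

test_that("pure forward and pure backward patterns separate exactly", {
  set.seed(2)
  c_cm <- 480
  dA <- rnorm(40, 0, 0.05)
  fwd <- tibble::tibble(t_mid = (1:40) * 0.0096, dA = dA, dQ = c_cm * dA)
  sep <- separate_waves(fwd, c_cm / 100)
  expect_equal(sep$dA_minus, rep(0, 40), tolerance = 1e-14)
  expect_equal(sep$dI_minus, rep(0, 40), tolerance = 1e-14)
  expect_equal(sep$dA_plus, dA, tolerance = 1e-14)

  bwd <- tibble::tibble(t_mid = (1:40) * 0.0096, dA = dA, dQ = -c_cm * dA)
  sepb <- separate_waves(bwd, c_cm / 100)
  expect_equal(sepb$dA_plus, rep(0, 40), tolerance = 1e-14)
  expect_equal(sepb$dA_minus, dA, tolerance = 1e-14)
})

test_that("separation is equivariant under consistent flow/wave-speed scaling", {
  set.seed(3)
  inc <- random_increments()
  k <- 2.7
  sep1 <- separate_waves(inc, 5)
  inc2 <- dplyr::mutate(inc, dQ = k * dQ)
  sep2 <- separate_waves(inc2, 5 * k)
  expect_equal(sep2$dA_plus, sep1$dA_plus, tolerance = 1e-12)
  expect_equal(sep2$dA_minus, sep1$dA_minus, tolerance = 1e-12)
})

test_that("cumulated area components reconstruct the area waveform", {
  set.seed(4)
  inc <- random_increments()
  sep <- separate_waves(inc, 6)
  comp <- cumulate_area(sep)
  expect_equal(comp$A_plus + comp$A_minus, cumsum(inc$dA), tolerance = 1e-12)
  # pure forward: backward component identically zero
  c_cm <- 600
  fwd <- tibble::tibble(t_mid = inc$t_mid, dA = inc$dA, dQ = c_cm * inc$dA)
  compf <- cumulate_area(separate_waves(fwd, 6))
  expect_equal(compf$A_minus, rep(0, nrow(fwd)), tolerance = 1e-13)
})

test_that("reflection magnitude is an amplitude ratio with the stated edge cases", {
  a_plus <- cumsum(c(0, 0.1, 0.2, 0.1, -0.1, -0.2, -0.1))
  expect_equal(reflection_magnitude(a_plus, 0.3 * a_plus), 0.3,
               tolerance = 1e-12)
  expect_equal(reflection_magnitude(a_plus, a_plus), 1, tolerance = 1e-12)
  expect_equal(reflection_magnitude(a_plus, rep(0, length(a_plus))), 0)
  expect_error(reflection_magnitude(rep(1, 5), a_plus[1:5]),
               class = "coawave_error_separation")
})

test_that("an injected backward compression wave is detected and quantified", {
  period <- 0.8
  dt <- 0.0096
  tpl <- make_forward_wave(period, dt, 80)
  fwd <- tibble::tibble(
    t_mid = (tpl$time[-nrow(tpl)] + tpl$time[-1]) / 2,
    dQ = diff(tpl$flow)
  )
  pwv <- 5.5
  for (mag in c(0.5, 2, 5)) {
    built <- inject_backward_wave(fwd, pwv, mag, arrival = 0.12, width = 0.012)
    sep <- separate_waves(built[, c("t_mid", "dA", "dQ")], pwv)
    waves <- detect_waves(sep)
    bcw <- waves[waves$kind == "BCW", ]
    expect_equal(nrow(bcw), 1L)
    expect_equal(bcw$magnitude, mag, tolerance = 0.1 * mag)
    expect_lt(abs(bcw$t_peak - 0.12), dt + 1e-9)
  }
  # magnitude zero leaves a pure forward pattern: one FCW, one FEW, nothing else
  pure <- inject_backward_wave(fwd, pwv, 0, arrival = 0.12, width = 0.012)
  expect_equal(pure$dQ, pwv * 100 * pure$dA, tolerance = 1e-12)
  wpure <- detect_waves(separate_waves(pure[, c("t_mid", "dA", "dQ")], pwv))
  expect_setequal(wpure$kind, c("FCW", "FEW"))

  zero <- separate_waves(tibble::tibble(t_mid = fwd$t_mid,
                                        dA = 0 * fwd$dQ, dQ = 0 * fwd$dQ), pwv)
  expect_equal(nrow(detect_waves(zero)), 0L)
})

test_that("bcw_summary picks the largest in-systole BCW and handles absence", {
  none <- tibble::tibble(kind = c("FCW", "FEW"), t_onset = c(0.05, 0.25),
                         t_peak = c(0.08, 0.28), t_end = c(0.2, 0.33),
                         magnitude = c(30, 28), peak_intensity = c(4, 4))
  out <- bcw_summary(none)
  expect_equal(out$bcw_magnitude, 0)
  expect_true(is.na(out$bcw_time))

  two <- dplyr::bind_rows(none, tibble::tibble(
    kind = "BCW", t_onset = c(0.07, 0.15), t_peak = c(0.09, 0.17),
    t_end = c(0.11, 0.19), magnitude = c(1.2, 3.4), peak_intensity = c(1, 2)
  ))
  out2 <- bcw_summary(two)
  expect_equal(out2$bcw_magnitude, 3.4)
  expect_equal(out2$bcw_time, 0.17)

  # the systole gate drops waves whose peak falls outside the flow window
  cyc <- make_cycle()
  late <- tibble::tibble(kind = "BCW", t_onset = 0.5, t_peak = 0.6,
                         t_end = 0.7, magnitude = 9, peak_intensity = 3)
  gated <- bcw_summary(dplyr::bind_rows(two, late), cycle = cyc)
  expect_equal(gated$bcw_magnitude, 3.4)
})

test_that("wave_analysis composes the stages and its tidiers work", {
  set.seed(21)
  s <- synthesize_subject(noiseless_params(), "patient")
  fit <- calibrate_beta(s$record$cycle, s$record$bp)
  a_d <- min(s$record$cycle$area)
  pwv <- bramwell_hill_pwv(a_d, max(s$record$cycle$area) - a_d,
                           fit$csbp - s$record$bp$dbp)
  wa <- wave_analysis(s$record$cycle, pwv)
  expect_s3_class(tidy(wa), "tbl_df")
  expect_equal(glance(wa)$bcw_magnitude, wa$bcw_magnitude)
  expect_equal(wa$reflection_magnitude,
               wa$area_backward_amplitude / wa$area_forward_amplitude,
               tolerance = 1e-12)
  expect_s3_class(autoplot(wa), "ggplot")
})
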