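two_level_cycle <- function(a_d = 5, a_s = 6, n = 32) {
  # piecewise cycle whose samples attain a_d and a_s exactly
  t <- (seq_len(n) - 1) * 0.0096
  up <- c(0, 0.25, 0.6, 0.9)
  shape <- c(rep(0, 6), up, rep(1, 6), rev(up), rep(0, n - 20))
  aortic_cycle(tibble::tibble(
    time = t,
    area = a_d + (a_s - a_d) * shape,
    flow = 300 * shape
  ))
}

test_that("synthesized pressure follows the exponential pressure-area model", {
  t <- (0:19) * 0.0096
  flat <- aortic_cycle(tibble::tibble(time = t, area = rep(5, 20),
                                      flow = rep(0, 20)))
  expect_equal(synthesize_pressure(flat, 80, 3), rep(80, 20))

  cyc <- two_level_cycle()
  expect_equal(synthesize_pressure(cyc, 80, 1e-12), rep(80, nrow(cyc)),
               tolerance = 1e-9)

  # beta chosen to map A_s = 6 onto 140 mmHg: beta = ln(140/80) * 5 / 1
  beta <- log(140 / 80) * 5
  p <- synthesize_pressure(cyc, 80, beta)
  expect_equal(max(p), 140, tolerance = 1e-9)
  expect_true(all(p >= 80))
  expect_equal(p[which.min(cyc$area)], 80)
})

test_that("initial_beta inverts the model at the systolic area", {
  cyc <- two_level_cycle()
  bp <- brachial_bp(140, 80, 100)
  b0 <- initial_beta(cyc, bp)
  expect_equal(b0, 5 * log(1.75), tolerance = 1e-12)
  # its defining property: synthesized peak equals brachial systolic pressure
  expect_equal(max(synthesize_pressure(cyc, 80, b0)), 140, tolerance = 1e-9)

  # depends only on A_d / (A_s - A_d): doubling both areas with the
  # excursion scaled alike leaves beta0 unchanged
  cyc2 <- two_level_cycle(a_d = 10, a_s = 12)
  expect_equal(initial_beta(cyc2, bp), b0, tolerance = 1e-12)

  flat <- aortic_cycle(tibble::tibble(time = (0:19) * 0.0096,
                                      area = rep(5, 20), flow = rep(0, 20)))
  expect_error(initial_beta(flat, bp),
               class = "coawave_error_degenerate_waveform")
})

test_that("calibration recovers the generating beta and c-SBP exactly at zero noise", {
  set.seed(101)
  p0 <- noiseless_params()
  for (g in c("patient", "control")) {
    s <- synthesize_subject(p0, g)
    fit <- calibrate_beta(s$record$cycle, s$record$bp)
    expect_equal(fit$beta, s$truth$beta_true, tolerance = 1e-6)
    expect_equal(fit$csbp, s$truth$csbp_true, tolerance = 0.01)
    expect_lte(fit$mean_abs_error, 0.01)
    expect_lte(fit$csbp, s$record$bp$sbp)
    expect_lte(fit$beta, fit$beta0)
  }
})

test_that("calibration limits and infeasibility behave as the model dictates", {
  cyc <- two_level_cycle()
  # mbp barely above dbp: beta -> 0 and csbp -> dbp
  fit <- calibrate_beta(cyc, brachial_bp(140, 80, 80.05))
  expect_lt(fit$beta, 0.05)
  expect_lt(fit$csbp, 81)

  # mbp above the reachable mean at beta0 is infeasible by construction
  b0 <- initial_beta(cyc, brachial_bp(140, 80, 100))
  mean_max <- mean(synthesize_pressure(cyc, 80, b0))
  expect_error(calibrate_beta(cyc, brachial_bp(140, 80, mean_max + 1)),
               class = "coawave_error_calibration_infeasible")
})

test_that("the mean synthesized pressure is strictly increasing in beta", {
  set.seed(7)
  for (i in 1:6) {
    cyc <- make_cycle(a_d = runif(1, 4, 7), pulse_area = runif(1, 0.4, 1.2))
    betas <- seq(0.2, 6, length.out = 25)
    means <- vapply(betas, function(b) mean(synthesize_pressure(cyc, 75, b)),
                    numeric(1))
    expect_true(all(diff(means) > 0))
  }
})

test_that("bisection agrees with a dense grid-search oracle", {
  set.seed(31)
  p0 <- noiseless_params()
  for (i in 1:5) {
    s <- synthesize_subject(p0, sample(c("patient", "control"), 1))
    fit <- calibrate_beta(s$record$cycle, s$record$bp)
    oracle <- grid_search_beta(s$record$cycle, s$record$bp, n_grid = 1e4)
    grid_step <- fit$beta0 / 1e4
    expect_lt(abs(fit$beta - oracle), grid_step)
  }
})

test_that("tidy/glance/autoplot methods expose the fit", {
  cyc <- two_level_cycle()
  fit <- calibrate_beta(cyc, brachial_bp(140, 80, 88))
  td <- tidy(fit)
  expect_setequal(td$term, c("beta", "csbp", "mean_pressure"))
  gl <- glance(fit)
  expect_equal(gl$csbp, fit$csbp)
  expect_s3_class(autoplot(fit), "ggplot")
})
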