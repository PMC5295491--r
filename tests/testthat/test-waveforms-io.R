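test_that("aortic_cycle enforces its invariants with named errors", {
  t <- seq(0, by = 0.0096, length.out = 20)
  ok <- tibble::tibble(time = t, area = 5 + t, flow = t)
  expect_s3_class(aortic_cycle(ok), "aortic_cycle")

  expect_error(aortic_cycle(ok[1:10, ]), class = "coawave_error_length")
  expect_error(aortic_cycle(dplyr::mutate(ok, time = time^1.01)),
               class = "coawave_error_time_grid")
  expect_error(aortic_cycle(dplyr::mutate(ok, time = time + 0.01)),
               class = "coawave_error_time_grid")
  bad_area <- ok
  bad_area$area[5] <- 0
  expect_error(aortic_cycle(bad_area), class = "coawave_error_area")
  expect_error(aortic_cycle(ok[, c("time", "area")]),
               class = "coawave_error_column")
  # alias columns are accepted
  alias <- tibble::tibble(time_s = t, area_cm2 = 5 + t, flow_ml_s = t)
  expect_equal(aortic_cycle(alias)$area, 5 + t)
})

test_that("brachial_bp enforces pressure ordering", {
  expect_error(brachial_bp(140, 80, 75), class = "coawave_error_bp_ordering")
  expect_error(brachial_bp(140, -1, 90), class = "coawave_error_bp")
  bp <- brachial_bp(140, 80, 95)
  expect_equal(bp$mbp, 95)
  expect_equal(estimate_mbp(140, 80), 100)
})

test_that("subject files round-trip through CSV + JSON to 1e-9", {
  dir <- withr::local_tempdir()
  set.seed(11)
  s <- synthesize_subject(cohort_params(), "patient", "RT01")
  write_subject_csv(s$record, dir)
  back <- read_subject_csv(file.path(dir, "RT01.csv"))
  expect_equal(back$cycle$area, s$record$cycle$area, tolerance = 1e-9)
  expect_equal(back$cycle$flow, s$record$cycle$flow, tolerance = 1e-9)
  expect_equal(back$cycle$time, s$record$cycle$time, tolerance = 1e-9)
  expect_equal(cycle_period(back$cycle), cycle_period(s$record$cycle),
               tolerance = 1e-9)
  expect_equal(back$bp$mbp, s$record$bp$mbp, tolerance = 1e-9)
  expect_equal(back$bsa, s$record$bsa, tolerance = 1e-9)
  expect_equal(back$group, "patient")
  expect_error(read_subject_csv(file.path(dir, "missing.csv")),
               class = "coawave_error_io")
})

test_that("resample_uniform is the identity at the native grid and exact on ramps", {
  cyc <- make_cycle()
  same <- resample_uniform(cyc, cycle_dt(cyc))
  expect_equal(same$area, cyc$area, tolerance = 1e-12)
  expect_equal(same$time, cyc$time, tolerance = 1e-12)

  t <- seq(0, by = 0.01, length.out = 32)
  ramp <- aortic_cycle(tibble::tibble(time = t, area = 4 + 2 * t, flow = 10 * t))
  half <- resample_uniform(ramp, 0.005)
  mid_idx <- seq(2, nrow(half), by = 2)  # midpoints of the original intervals
  expect_equal(half$area[mid_idx], 4 + 2 * (t[-length(t)] + 0.005),
               tolerance = 1e-12)

  expect_error(resample_uniform(ramp, cycle_period(ramp) / 4),
               class = "coawave_error_resample")
})

test_that("smoothing reproduces polynomials up to its order and validates the window", {
  t <- seq(0, by = 0.0096, length.out = 60)
  const <- aortic_cycle(tibble::tibble(time = t, area = rep(6, 60),
                                       flow = rep(100, 60)))
  sm <- smooth_cycle(const, window = 9, polyorder = 3)
  expect_equal(sm$area, const$area, tolerance = 1e-12)

  quad <- aortic_cycle(tibble::tibble(time = t, area = 5 + 3 * t - 8 * t^2,
                                      flow = 200 * t^2))
  smq <- smooth_cycle(quad, window = 11, polyorder = 2)
  expect_equal(smq$area, quad$area, tolerance = 1e-10)
  expect_equal(smq$flow, quad$flow, tolerance = 1e-10)

  expect_error(smooth_cycle(quad, window = 4), class = "coawave_error_smooth")
  expect_error(smooth_cycle(quad, window = 3, polyorder = 3),
               class = "coawave_error_smooth")
})

test_that("increments are first differences at midpoints and telescope exactly", {
  t <- seq(0, by = 0.0096, length.out = 18)
  cyc <- aortic_cycle(tibble::tibble(
    time = t, area = c(5.0, 5.2, 5.1, rep(5.1, 15)), flow = rep(7, 18)
  ))
  inc <- increments(cyc)
  expect_equal(inc$dA[1:2], c(0.2, -0.1), tolerance = 1e-12)
  expect_equal(inc$dQ, rep(0, 17))
  expect_equal(inc$t_mid[1], 0.0048, tolerance = 1e-12)
  expect_equal(sum(inc$dA), cyc$area[18] - cyc$area[1], tolerance = 1e-12)

  # linearity per channel on random cycles
  set.seed(42)
  for (i in 1:5) {
    base <- make_cycle(a_d = runif(1, 4, 7), q_peak = runif(1, 300, 500))
    a <- runif(1, 0.5, 3)
    scaled <- aortic_cycle(tibble::tibble(
      time = base$time, area = a * base$area, flow = a * base$flow
    ))
    expect_equal(increments(scaled)$dA, a * increments(base)$dA,
                 tolerance = 1e-12)
    expect_equal(increments(scaled)$dQ, a * increments(base)$dQ,
                 tolerance = 1e-12)
  }
})
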