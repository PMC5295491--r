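test_that("the per-subject pipeline recovers ground truth at zero noise", {
  set.seed(55)
  p0 <- noiseless_params()
  s <- synthesize_subject(p0, "patient")
  m <- analyze_subject(s$record)
  tr <- s$truth
  expect_equal(m$beta, tr$beta_true, tolerance = 1e-6)
  expect_equal(m$csbp, tr$csbp_true, tolerance = 0.01)
  expect_equal(m$pwv, tr$c_chord_true, tolerance = 1e-4)
  expect_equal(m$resistance, tr$resistance_true, tolerance = 1e-6)
  expect_equal(m$tac_central, tr$tac_true, tolerance = 0.01 * tr$tac_true)
  expect_equal(m$bcw_magnitude, tr$bcw_magnitude_true,
               tolerance = 0.1 * tr$bcw_magnitude_true)
  expect_equal(m$bcw_time, tr$bcw_time_true, tolerance = 0.0096 + 1e-9)
  expect_true(is.na(m$failure_reason))
})

test_that("missing diameters leave morphology indices missing, the rest computed", {
  set.seed(56)
  s <- synthesize_subject(cohort_params(), "control")
  m <- analyze_subject(s$record)
  expect_true(is.na(m$ti) && is.na(m$ci))
  expect_false(is.na(m$csbp))
  expect_false(is.na(m$tac_central))
})

test_that("hypertension classification is a strict threshold on systolic pressures", {
  set.seed(57)
  s <- synthesize_subject(noiseless_params(), "patient")
  m <- analyze_subject(s$record)
  expect_identical(m$central_htn, m$csbp > 125)
  expect_identical(m$brachial_htn, m$psbp > 140)

  # strictness at the boundary: a threshold equal to the measured value
  # does not flag; one just below does
  at <- analyze_subject(s$record,
                        analysis_config(central_htn_threshold = m$csbp,
                                        brachial_htn_threshold = m$psbp))
  expect_false(at$central_htn)
  expect_false(at$brachial_htn)
  below <- analyze_subject(s$record,
                           analysis_config(central_htn_threshold = m$csbp - 1e-9,
                                           brachial_htn_threshold = m$psbp - 1e-9))
  expect_true(below$central_htn)
  expect_true(below$brachial_htn)
})

test_that("group summaries: identical groups give equal means and p near 1", {
  set.seed(58)
  x <- rnorm(12, 100, 8)
  metrics <- tibble::tibble(
    group = rep(c("patient", "control"), each = 12),
    csbp = c(x, x),
    central_htn = rep(c(TRUE, FALSE), 12)
  )
  gs <- summarize_groups(metrics, vars = "csbp", log_vars = character(),
                         binary_vars = "central_htn")
  num <- gs[gs$metric == "csbp", ]
  expect_equal(num$mean_patient, num$mean_control, tolerance = 1e-12)
  expect_equal(num$p_value, 1, tolerance = 1e-9)
  expect_equal(gs$p_value[gs$metric == "central_htn"], 1, tolerance = 1e-9)
})

test_that("log-scale metrics reject non-positive values explicitly", {
  metrics <- tibble::tibble(
    group = rep(c("patient", "control"), each = 5),
    bcw_magnitude = c(1, 2, 0, 1, 2, 1, 1, 1, 2, 1)
  )
  expect_error(summarize_groups(metrics, vars = "bcw_magnitude"),
               class = "coawave_error_log_transform")
})

test_that("summaries need two groups with at least two subjects each", {
  one <- tibble::tibble(group = c("patient", "patient", "control"),
                        csbp = c(100, 110, 105))
  expect_error(summarize_groups(one, vars = "csbp", log_vars = character()),
               class = "coawave_error_groups")
})

test_that("LVM regression recovers the generative slope exactly at zero LVM noise", {
  p <- noiseless_params(
    n_patients = 20, n_controls = 10, seed = 9,
    lvm_model = list(intercept = 50, slope_log_bcw = 18, slope_bsa = 50,
                     sex_offset = 15, noise_sd = 0)
  )
  coh <- generate_cohort(p)
  tr <- coh$truth
  metrics <- tibble::tibble(
    group = tr$group, lvm = tr$lvm_true,
    bcw_magnitude_log = log(tr$bcw_magnitude_true),
    bsa = tr$bsa, age = tr$age, sex = tr$sex
  )
  fit <- suppressWarnings(lvm_regression(metrics))  # perfect-fit warning
  expect_equal(fit$predictor_row$estimate, 18, tolerance = 1e-6)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_gt(suppressWarnings(glance(fit))$r.squared, 0.999)
})

test_that("rank-deficient LVM models are reported with the offending column", {
  set.seed(60)
  metrics <- tibble::tibble(
    group = rep(c("patient", "control"), each = 10),
    lvm = rnorm(20, 120, 10),
    bcw_magnitude_log = rnorm(20),
    bsa = rnorm(20, 1.8, 0.1),
    age = rnorm(20, 30, 5),
    sex = sample(c("M", "F"), 20, TRUE),
    dup = 1  # constant column is collinear with the intercept
  )
  expect_error(lvm_regression(metrics, adjusters = c("bsa", "age", "sex", "dup")),
               class = "coawave_error_rank_deficient")
  expect_error(lvm_regression(metrics[1:5, ]),
               class = "coawave_error_regression")
})

test_that("stage failures are logged per subject, not fatal", {
  set.seed(61)
  s <- synthesize_subject(cohort_params(), "patient")
  # corrupt the brachial mean so that calibration is infeasible
  bad <- s$record
  mean_max <- mean(synthesize_pressure(bad$cycle, bad$bp$dbp,
                                       initial_beta(bad$cycle, bad$bp)))
  bad$bp <- brachial_bp(bad$bp$sbp, bad$bp$dbp, mean_max + 5)
  expect_warning(m <- analyze_subject(bad), "calibration")
  expect_true(is.na(m$csbp))
  expect_match(m$failure_reason, "infeasible")
})
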