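#' Analysis configuration
#'
#' @param tol Mean-pressure tolerance for [calibrate_beta()], mmHg.
#' @param smooth Optional smoothing before analysis: `NULL` (default, no
#'   smoothing) or a list `list(window =, polyorder =)` passed to
#'   [smooth_cycle()].
#' @param min_peak_fraction Wave-support threshold for [detect_waves()].
#' @param flow_fraction Systole gate for [bcw_summary()].
#' @param central_htn_threshold Central systolic hypertension cut-off, mmHg
#'   (c-SBP > 125).
#' @param brachial_htn_threshold Brachial systolic hypertension cut-off,
#'   mmHg (p-SBP > 140).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(tol = 0.01, smooth = NULL,
                            min_peak_fraction = 0.05, flow_fraction = 0.05,
                            central_htn_threshold = 125,
                            brachial_htn_threshold = 140) {
  structure(list(tol = tol, smooth = smooth,
                 min_peak_fraction = min_peak_fraction,
                 flow_fraction = flow_fraction,
                 central_htn_threshold = central_htn_threshold,
                 brachial_htn_threshold = brachial_htn_threshold),
            class = "analysis_config")
}

#' Run the full per-subject pipeline
#'
#' Central pressure calibration, afterload summary and wave intensity
#' analysis for one subject, returning all study metrics as a one-row
#' tibble. A failing stage leaves its metrics missing and records the reason
#' in `failure_reason` (with a warning naming the subject) rather than
#' aborting the batch.
#'
#' @param record A [subject_record()].
#' @param config An [analysis_config()].
#' @return One-row tibble of subject metrics; `bcw_magnitude_log` is the
#'   natural log of the BCW magnitude (`NA` when no BCW was detected);
#'   `central_htn` is `csbp > 125` and `brachial_htn` is `psbp > 140` at the
#'   default thresholds.
#' @export
analyze_subject <- function(record, config = analysis_config()) {
  stopifnot(inherits(record, "subject_record"))
  cycle <- record$cycle
  if (!is.null(config$smooth)) {
    cycle <- smooth_cycle(cycle, config$smooth$window, config$smooth$polyorder)
  }
  out <- tibble::tibble(
    id = record$id, group = record$group,
    psbp = record$bp$sbp, dbp = record$bp$dbp, mbp = record$bp$mbp,
    bsa = record$bsa, sex = record$sex, age = record$age, lvm = record$lvm,
    heart_rate = record$heart_rate,
    beta = NA_real_, csbp = NA_real_, pwv = NA_real_, zc = NA_real_,
    stroke_volume = NA_real_, cardiac_output = NA_real_,
    cardiac_index = NA_real_,
    resistance = NA_real_, resistance_indexed = NA_real_,
    tac_central = NA_real_, tac_brachial = NA_real_,
    tac_central_indexed = NA_real_, tac_brachial_indexed = NA_real_,
    pp_central = NA_real_, pp_brachial = NA_real_,
    bcw_magnitude = NA_real_, bcw_magnitude_log = NA_real_,
    bcw_time = NA_real_,
    fcw_magnitude = NA_real_, few_magnitude = NA_real_,
    reflection_magnitude = NA_real_,
    ti = NA_real_, ci = NA_real_, recoarctation_suspected = NA,
    central_htn = NA, brachial_htn = NA,
    failure_reason = NA_character_
  )
  fail <- function(stage, e) {
    msg <- sprintf("%s failed for subject %s: %s", stage, record$id,
                   conditionMessage(e))
    warning(msg, call. = FALSE)
    msg
  }

  fit <- tryCatch(calibrate_beta(cycle, record$bp, tol = config$tol),
                  error = function(e) e)
  if (inherits(fit, "error")) {
    out$failure_reason <- fail("central pressure calibration", fit)
    return(out)
  }
  out$beta <- fit$beta
  out$csbp <- fit$csbp
  out$central_htn <- fit$csbp > config$central_htn_threshold
  out$brachial_htn <- record$bp$sbp > config$brachial_htn_threshold

  load <- tryCatch(afterload_summary(cycle, record$bp, fit$csbp, record$bsa),
                   error = function(e) e)
  if (inherits(load, "error")) {
    out$failure_reason <- fail("afterload", load)
  } else {
    for (nm in names(load)) out[[nm]] <- load[[nm]]
  }

  wia <- tryCatch(
    wave_analysis(cycle, out$pwv, config$min_peak_fraction,
                  config$flow_fraction),
    error = function(e) e
  )
  if (inherits(wia, "error")) {
    out$failure_reason <- fail("wave intensity", wia)
  } else {
    out$bcw_magnitude <- wia$bcw_magnitude
    out$bcw_magnitude_log <- ifelse(wia$bcw_magnitude > 0,
                                    log(wia$bcw_magnitude), NA_real_)
    out$bcw_time <- wia$bcw_time
    out$fcw_magnitude <- wia$fcw_magnitude
    out$few_magnitude <- wia$few_magnitude
    out$reflection_magnitude <- wia$reflection_magnitude
  }

  morph <- morphology_indices(record$diam_transverse, record$diam_isthmus,
                              record$diam_descending)
  out$ti <- morph$ti
  out$ci <- morph$ci
  out$recoarctation_suspected <- morph$recoarctation_suspected
  out
}

#' @rdname analyze_subject
#' @param subjects A list of [subject_record()]s or a `coawave_cohort`.
#' @export
analyze_cohort <- function(subjects, config = analysis_config()) {
  if (inherits(subjects, "coawave_cohort")) subjects <- subjects$subjects
  purrr::map_dfr(subjects, analyze_subject, config = config)
}

#' Group summaries and two-sample comparisons
#'
#' For each requested metric: group means with 95% confidence intervals
#' (geometric mean and CI on the log scale for metrics in `log_vars`, as is
#' conventional for right-skewed hemodynamic measures), plus both the Welch
#' and the pooled-variance two-sample t-test. The reported `p_value` uses
#' the Welch correction when the group variance ratio exceeds 2, the pooled
#' test otherwise. Binary metrics get counts, proportions and a two-sample
#' proportions test.
#'
#' @param metrics Tibble from [analyze_cohort()] with a `group` column.
#' @param vars Numeric metric columns to summarise (default: a standard set
#'   of hemodynamic metrics present in `metrics`).
#' @param log_vars Metrics compared on the log scale; any non-positive value
#'   there is an explicit error.
#' @param binary_vars Logical metrics compared as proportions.
#' @return A tidy tibble, one row per metric.
#' @export
summarize_groups <- function(metrics,
                             vars = NULL,
                             log_vars = c("bcw_magnitude", "fcw_magnitude",
                                          "few_magnitude",
                                          "reflection_magnitude"),
                             binary_vars = c("central_htn", "brachial_htn")) {
  stopifnot("group" %in% names(metrics))
  groups <- unique(metrics$group)
  if (length(groups) != 2L) {
    abort("summarize_groups needs exactly two groups",
          class = "coawave_error_groups")
  }
  if (min(table(metrics$group)) < 2L) {
    abort("each group needs at least 2 subjects",
          class = "coawave_error_groups")
  }
  if (is.null(vars)) {
    candidates <- c("csbp", "psbp", "dbp", "mbp", "pwv", "zc",
                    "cardiac_index", "resistance_indexed",
                    "tac_central", "tac_brachial",
                    "tac_central_indexed", "tac_brachial_indexed",
                    "bcw_magnitude", "bcw_time", "fcw_magnitude",
                    "few_magnitude", "reflection_magnitude", "lvm")
    vars <- intersect(candidates, names(metrics))
  }
  log_vars <- intersect(log_vars, vars)

  pat <- metrics[metrics$group == "patient", , drop = FALSE]
  ctl <- metrics[metrics$group == "control", , drop = FALSE]

  ci_of <- function(x) {
    x <- x[!is.na(x)]
    m <- mean(x)
    half <- qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
    c(mean = m, lo = m - half, hi = m + half)
  }

  num_rows <- purrr::map_dfr(vars, function(v) {
    xp <- pat[[v]]
    xc <- ctl[[v]]
    on_log <- v %in% log_vars
    if (on_log) {
      bad <- c(xp, xc)
      if (any(!is.na(bad) & bad <= 0)) {
        abort(sprintf("nonpositive value under log transform for metric '%s'", v),
              class = "coawave_error_log_transform")
      }
      xp <- log(xp)
      xc <- log(xc)
    }
    xp <- xp[!is.na(xp)]
    xc <- xc[!is.na(xc)]
    sp <- ci_of(xp)
    sc <- ci_of(xc)
    if (on_log) {
      sp <- exp(sp)
      sc <- exp(sc)
    }
    p_welch <- tryCatch(t.test(xp, xc, var.equal = FALSE)$p.value,
                        error = function(e) NA_real_)
    p_pooled <- tryCatch(t.test(xp, xc, var.equal = TRUE)$p.value,
                         error = function(e) NA_real_)
    vr <- max(var(xp), var(xc)) / min(var(xp), var(xc))
    tibble::tibble(
      metric = v, scale = if (on_log) "geometric" else "arithmetic",
      n_patient = length(xp), n_control = length(xc),
      mean_patient = sp[["mean"]], ci_lo_patient = sp[["lo"]],
      ci_hi_patient = sp[["hi"]],
      mean_control = sc[["mean"]], ci_lo_control = sc[["lo"]],
      ci_hi_control = sc[["hi"]],
      variance_ratio = vr,
      test = if (is.finite(vr) && vr > 2) "welch" else "pooled",
      p_welch = p_welch, p_pooled = p_pooled,
      p_value = if (is.finite(vr) && vr > 2) p_welch else p_pooled
    )
  })

  bin_rows <- purrr::map_dfr(intersect(binary_vars, names(metrics)), function(v) {
    xp <- pat[[v]]
    xc <- ctl[[v]]
    xp <- xp[!is.na(xp)]
    xc <- xc[!is.na(xc)]
    tab <- matrix(c(sum(xp), length(xp) - sum(xp),
                    sum(xc), length(xc) - sum(xc)),
                  nrow = 2, byrow = TRUE)
    p <- tryCatch(suppressWarnings(stats::prop.test(tab)$p.value),
                  error = function(e) NA_real_)
    tibble::tibble(
      metric = v, scale = "proportion",
      n_patient = length(xp), n_control = length(xc),
      mean_patient = mean(xp), ci_lo_patient = NA_real_,
      ci_hi_patient = NA_real_,
      mean_control = mean(xc), ci_lo_control = NA_real_,
      ci_hi_control = NA_real_,
      variance_ratio = NA_real_, test = "proportions",
      p_welch = NA_real_, p_pooled = NA_real_, p_value = p
    )
  })
  dplyr::bind_rows(num_rows, bin_rows)
}

#' Adjusted linear regression of left ventricular mass
#'
#' Ordinary least squares of LVM (g) on a hemodynamic predictor (by default
#' the natural-log BCW magnitude) adjusted for body surface area, age, sex
#' and case/control status. Rank deficiency is reported with the offending
#' columns rather than silently dropped.
#'
#' @param metrics Tibble with `lvm`, the predictor and adjuster columns.
#' @param predictor Name of the predictor column (default
#'   `"bcw_magnitude_log"`).
#' @param adjusters Adjustment covariates (default BSA, age, sex, group).
#' @return A list of class `lvm_fit` with the underlying `lm` (`$fit`), the
#'   coefficient table (`$coefficients`) and the predictor row
#'   (`$predictor_row`); `tidy()` returns the coefficient table.
#' @export
lvm_regression <- function(metrics, predictor = "bcw_magnitude_log",
                           adjusters = c("bsa", "age", "sex", "group")) {
  cols <- c("lvm", predictor, adjusters)
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          class = "coawave_error_column")
  }
  df <- metrics[cols]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (nrow(df) < 10L) {
    abort(sprintf("LVM regression needs >= 10 complete subjects, got %d", nrow(df)),
          class = "coawave_error_regression")
  }
  fml <- stats::reformulate(c(predictor, adjusters), response = "lvm")
  fit <- lm(fml, data = df)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("rank-deficient LVM model; offending column(s): ",
                 paste(bad, collapse = ", ")),
          class = "coawave_error_rank_deficient")
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm), estimate = unname(sm[, 1]),
    std.error = unname(sm[, 2]), statistic = unname(sm[, 3]),
    p.value = unname(sm[, 4])
  )
  structure(list(fit = fit, coefficients = coefs,
                 predictor = predictor,
                 predictor_row = coefs[coefs$term == predictor, ]),
            class = "lvm_fit")
}

#' @rdname lvm_regression
#' @param predictors Character vector of metric columns; each is fit with
#'   the same adjusters, mirroring a univariable-association table.
#' @return `lvm_univariable()` returns one row per predictor (its adjusted
#'   coefficient, SE and p-value).
#' @export
lvm_univariable <- function(metrics, predictors,
                            adjusters = c("bsa", "age", "sex", "group")) {
  purrr::map_dfr(predictors, function(p) {
    row <- lvm_regression(metrics, predictor = p, adjusters = adjusters)$predictor_row
    dplyr::mutate(row, predictor = p, .before = 1)
  })
}

#' @export
print.lvm_fit <- function(x, ...) {
  cat("<lvm_fit>\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.lvm_fit <- function(x, ...) x$coefficients

#' @export
glance.lvm_fit <- function(x, ...) {
  sm <- summary(x$fit)
  tibble::tibble(r.squared = sm$r.squared, adj.r.squared = sm$adj.r.squared,
                 sigma = sm$sigma, nobs = stats::nobs(x$fit))
}
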