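#' Construct a single-cycle aortic waveform
#'
#' An `aortic_cycle` is a tibble with columns `time` (s), `area` (cm^2) and
#' `flow` (mL/s), sampled on a strictly uniform grid starting at `time = 0`
#' (the R-wave trigger). The cycle length (`period`) extends one sample
#' interval past the last sample, so that `period = n * dt`; the cycle is
#' treated as periodic wherever a full-cycle integral is needed and diastolic
#' decay beyond the acquired samples is never extrapolated.
#'
#' @param data A data frame with columns `time`, `area`, `flow` (aliases
#'   `time_s`, `area_cm2`, `flow_ml_s` are accepted and renamed).
#' @param period Cycle length in seconds. Defaults to `last time + dt`.
#'
#' @return A tibble of class `aortic_cycle` with attributes `period` and `dt`.
#' @examples
#' t <- seq(0, 0.76, by = 0.0096 / 2)[1:64]
#' cyc <- aortic_cycle(tibble::tibble(
#'   time = t - t[1],
#'   area = 5 + 0.5 * sin(pi * pmin(t / 0.3, 1))^2,
#'   flow = 300 * sin(pi * pmin(t / 0.3, 1))^2
#' ))
#' cycle_dt(cyc)
#' @export
aortic_cycle <- function(data, period = NULL) {
  data <- as_cycle_frame(data)
  n <- nrow(data)
  if (n < 16L) {
    abort(sprintf("aortic_cycle needs >= 16 samples, got %d", n),
          class = "coawave_error_length")
  }
  dt <- infer_uniform_dt(data$time)
  if (is.null(period)) period <- data$time[n] + dt
  validate_cycle_values(data, period, dt)
  out <- tibble::new_tibble(data, nrow = n, class = "aortic_cycle")
  attr(out, "period") <- period
  attr(out, "dt") <- dt
  out
}

as_cycle_frame <- function(data) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame with time, area and flow columns",
          class = "coawave_error_column")
  }
  nm <- names(data)
  alias <- c(time_s = "time", area_cm2 = "area", flow_ml_s = "flow")
  for (a in names(alias)) {
    if (a %in% nm && !(alias[[a]] %in% nm)) names(data)[nm == a] <- alias[[a]]
    nm <- names(data)
  }
  missing <- setdiff(c("time", "area", "flow"), names(data))
  if (length(missing)) {
    abort(paste0("missing waveform column(s): ", paste(missing, collapse = ", ")),
          class = "coawave_error_column")
  }
  tibble::as_tibble(data[c("time", "area", "flow")])
}

infer_uniform_dt <- function(time, tol = 1e-9) {
  if (anyNA(time) || !all(is.finite(time))) {
    abort("time contains non-finite values", class = "coawave_error_time_grid")
  }
  d <- diff(time)
  if (any(d <= 0)) {
    abort("time must be strictly increasing", class = "coawave_error_time_grid")
  }
  dt <- (time[length(time)] - time[1]) / (length(time) - 1)
  if (max(abs(d - dt)) > tol) {
    abort(sprintf("time grid not uniform (max deviation %.3g s > %.0e s)",
                  max(abs(d - dt)), tol),
          class = "coawave_error_time_grid")
  }
  dt
}

validate_cycle_values <- function(data, period, dt) {
  if (abs(data$time[1]) > 1e-12) {
    abort("time must start at 0 (R-wave trigger origin)",
          class = "coawave_error_time_grid")
  }
  if (anyNA(data$area) || !all(is.finite(data$area)) || any(data$area <= 0)) {
    abort("non-positive or non-finite area sample",
          class = "coawave_error_area")
  }
  if (anyNA(data$flow) || !all(is.finite(data$flow))) {
    abort("non-finite flow sample", class = "coawave_error_flow")
  }
  if (!is.numeric(period) || length(period) != 1L || period <= data$time[nrow(data)]) {
    abort("period must be a single number beyond the last sample time",
          class = "coawave_error_time_grid")
  }
  invisible(TRUE)
}

#' @rdname aortic_cycle
#' @param cycle An `aortic_cycle`.
#' @export
cycle_period <- function(cycle) attr(cycle, "period")

#' @rdname aortic_cycle
#' @export
cycle_dt <- function(cycle) attr(cycle, "dt")

#' Full-cycle integral and time average under periodic extension
#'
#' On the uniform grid with `period = n * dt` and cyclic wrap, the
#' trapezoidal integral over one period reduces exactly to `dt * sum(x)` and
#' the time average to `mean(x)`. These are the integral conventions used by
#' every stage (stroke volume, mean pressure, windkessel forcing), so the
#' generator and the analysis agree to machine precision.
#'
#' @param cycle An `aortic_cycle`.
#' @param values Numeric vector aligned with the cycle samples.
#' @return A single number.
#' @export
cycle_integral <- function(cycle, values) {
  stopifnot(length(values) == nrow(cycle))
  cycle_dt(cycle) * sum(values)
}

#' @rdname cycle_integral
#' @export
cycle_mean <- function(cycle, values) {
  stopifnot(length(values) == nrow(cycle))
  mean(values)
}

#' Brachial oscillometric blood pressure
#'
#' Systolic, diastolic and measured mean brachial pressure (mmHg), as
#' obtained by automated oscillometric sphygmomanometry. The measured mean is
#' used as-is for calibration; it is never re-derived from a form factor
#' unless [estimate_mbp()] is called explicitly.
#'
#' @param sbp,dbp,mbp Pressures in mmHg with `dbp < mbp < sbp`.
#' @return A list of class `brachial_bp`.
#' @examples
#' brachial_bp(sbp = 120, dbp = 70, mbp = 88)
#' @export
brachial_bp <- function(sbp, dbp, mbp) {
  for (nmv in list(c("sbp", sbp), c("dbp", dbp), c("mbp", mbp))) {
    v <- as.numeric(nmv[[2]])
    if (length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("%s must be a single positive number", nmv[[1]]),
            class = "coawave_error_bp")
    }
  }
  if (!(dbp < mbp && mbp < sbp)) {
    abort(sprintf("BP ordering violated: need dbp < mbp < sbp, got %g / %g / %g",
                  dbp, mbp, sbp),
          class = "coawave_error_bp_ordering")
  }
  structure(list(sbp = as.numeric(sbp), dbp = as.numeric(dbp),
                 mbp = as.numeric(mbp)),
            class = "brachial_bp")
}

#' Fallback mean pressure from the one-third rule
#'
#' For datasets without a measured oscillometric mean, `mbp = dbp +
#' (sbp - dbp)/3`. Kept behind an explicit call so that a measured mean is
#' never silently replaced.
#'
#' @param sbp,dbp Systolic and diastolic pressure in mmHg.
#' @return Mean pressure in mmHg.
#' @export
estimate_mbp <- function(sbp, dbp) dbp + (sbp - dbp) / 3

#' Per-subject record
#'
#' Bundles the waveform cycle with brachial pressures, body surface area,
#' group label and optional covariates (left ventricular mass, arch
#' diameters). Heart rate is derived as `60 / period`.
#'
#' @param id Subject identifier (string).
#' @param group `"patient"` or `"control"`.
#' @param bsa Body surface area, m^2 (> 0).
#' @param bp A [brachial_bp()].
#' @param cycle An [aortic_cycle()].
#' @param sex `"M"` or `"F"`.
#' @param age Age in years.
#' @param lvm Left ventricular mass in grams (optional).
#' @param diam_transverse,diam_isthmus,diam_descending Arch diameters in mm
#'   (optional, all > 0 when present).
#' @return A list of class `subject_record`.
#' @export
subject_record <- function(id, group, bsa, bp, cycle, sex = NA_character_,
                           age = NA_real_, lvm = NA_real_,
                           diam_transverse = NA_real_, diam_isthmus = NA_real_,
                           diam_descending = NA_real_) {
  group <- match.arg(group, c("patient", "control"))
  if (!is.na(sex)) sex <- match.arg(sex, c("M", "F"))
  if (!is.numeric(bsa) || length(bsa) != 1L || !is.finite(bsa) || bsa <= 0) {
    abort("bsa must be a single positive number", class = "coawave_error_bsa")
  }
  if (!inherits(bp, "brachial_bp")) abort("bp must be a brachial_bp",
                                          class = "coawave_error_bp")
  if (!inherits(cycle, "aortic_cycle")) abort("cycle must be an aortic_cycle",
                                              class = "coawave_error_cycle")
  for (d in c("diam_transverse", "diam_isthmus", "diam_descending")) {
    v <- get(d)
    if (!is.na(v) && v <= 0) {
      abort(sprintf("%s must be positive when present", d),
            class = "coawave_error_diameter")
    }
  }
  structure(list(
    id = as.character(id), group = group, bsa = bsa, bp = bp, cycle = cycle,
    sex = sex, age = age, lvm = lvm,
    diam_transverse = diam_transverse, diam_isthmus = diam_isthmus,
    diam_descending = diam_descending,
    heart_rate = 60 / cycle_period(cycle)
  ), class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s (%s)>\n", x$id, x$group))
  cat(sprintf("  cycle: %d samples, dt %.4f s, period %.3f s (HR %.1f bpm)\n",
              nrow(x$cycle), cycle_dt(x$cycle), cycle_period(x$cycle),
              x$heart_rate))
  cat(sprintf("  BP %g/%g (mean %g) mmHg, BSA %.2f m2\n",
              x$bp$sbp, x$bp$dbp, x$bp$mbp, x$bsa))
  invisible(x)
}

#' @export
print.brachial_bp <- function(x, ...) {
  cat(sprintf("<brachial_bp %g/%g mmHg, mean %g mmHg>\n", x$sbp, x$dbp, x$mbp))
  invisible(x)
}

#' @rdname aortic_cycle
#' @param x Object to test.
#' @export
is_aortic_cycle <- function(x) inherits(x, "aortic_cycle")
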