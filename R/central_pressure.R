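#' Synthesize a central pressure curve from the area waveform
#'
#' Exponential pressure--area model: `p(t) = dbp * exp(beta * (A(t)/A_d - 1))`
#' with `A_d = min(area)` (diastolic anchor; ties broken by the earliest
#' sample). The synthesized pressure equals `dbp` wherever the area is at its
#' diastolic minimum and is everywhere at least `dbp`.
#'
#' @param cycle An [aortic_cycle()].
#' @param dbp Brachial diastolic pressure, mmHg (> 0).
#' @param beta Dimensionless scaling factor (> 0; `beta -> 0` gives a flat
#'   curve at `dbp`).
#' @return Numeric vector of pressures (mmHg), aligned with the cycle samples.
#' @export
synthesize_pressure <- function(cycle, dbp, beta) {
  stopifnot(is_aortic_cycle(cycle))
  if (!is.finite(dbp) || dbp <= 0) abort("dbp must be positive",
                                         class = "coawave_error_bp")
  if (!is.finite(beta) || beta < 0) abort("beta must be non-negative",
                                          class = "coawave_error_beta")
  a_d <- min(cycle$area)
  dbp * exp(beta * (cycle$area / a_d - 1))
}

#' Initial (maximal) scaling factor for the pressure--area model
#'
#' Inverts the exponential model at the systolic area so that the synthesized
#' peak equals brachial systolic pressure:
#' `beta0 = log(sbp/dbp) * A_d / (A_s - A_d)`. Because central systolic
#' pressure is in general lower than brachial systolic pressure, this is the
#' theoretical maximum of the scaling factor, and calibration only ever
#' reduces it.
#'
#' @param cycle An [aortic_cycle()].
#' @param bp A [brachial_bp()].
#' @return `beta0` (dimensionless).
#' @export
initial_beta <- function(cycle, bp) {
  stopifnot(is_aortic_cycle(cycle), inherits(bp, "brachial_bp"))
  a_d <- min(cycle$area)
  a_s <- max(cycle$area)
  if (a_s <= a_d) {
    abort("flat area waveform (A_s = A_d): non-pulsatile input",
          class = "coawave_error_degenerate_waveform")
  }
  log(bp$sbp / bp$dbp) * a_d / (a_s - a_d)
}

#' Calibrate the pressure--area scaling factor to the measured mean pressure
#'
#' Iteratively reduces the scaling factor from [initial_beta()] until the
#' time average of the synthesized pressure curve matches the measured
#' brachial mean pressure, exploiting the constancy of the diastolic-to-mean
#' pressure difference along the large arteries. The time-mean of the
#' synthesized curve is strictly increasing in `beta` (the exponential is
#' increasing and `A/A_d - 1 >= 0` with strict inequality somewhere), so the
#' calibration is a bisection on `[1e-6, beta0]`; the bracket is shrunk to
#' machine precision (or `max_iter`), and the result is accepted when the
#' mean-pressure residual is within `tol`. Central systolic pressure is the
#' peak of the calibrated curve and is guaranteed `<= sbp` because
#' `beta* <= beta0`.
#'
#' @param cycle An [aortic_cycle()].
#' @param bp A [brachial_bp()]; the measured mean is used as-is (see
#'   [estimate_mbp()] for datasets lacking one).
#' @param tol Pressure tolerance on the mean, mmHg (default 0.01).
#' @param max_iter Maximum bisection iterations (default 200).
#' @return An object of class `central_pressure_fit`: a list with `pressure`
#'   (tibble `time`, `pressure`), `beta`, `beta0`, `csbp`, `mean_pressure`,
#'   `mean_abs_error`, `iterations`, plus the inputs `dbp`, `mbp`.
#' @examples
#' cyc <- aortic_cycle(tibble::tibble(
#'   time = seq(0, by = 0.0096, length.out = 80),
#'   area = 5 + 0.8 * sin(pi * pmin(seq(0, by = 0.0096, length.out = 80) / 0.35, 1))^2,
#'   flow = 350 * sin(pi * pmin(seq(0, by = 0.0096, length.out = 80) / 0.30, 1))^2
#' ))
#' fit <- calibrate_beta(cyc, brachial_bp(125, 70, 92))
#' glance(fit)
#' @export
calibrate_beta <- function(cycle, bp, tol = 0.01, max_iter = 200L) {
  stopifnot(is_aortic_cycle(cycle), inherits(bp, "brachial_bp"))
  beta0 <- initial_beta(cycle, bp)
  if (beta0 <= 0) {
    abort("degenerate-waveform: beta0 = 0 (sbp = dbp), calibration impossible",
          class = "coawave_error_degenerate_waveform")
  }
  if (bp$mbp <= bp$dbp) {
    abort("mbp must exceed dbp", class = "coawave_error_bp_ordering")
  }
  mean_at <- function(beta) cycle_mean(cycle, synthesize_pressure(cycle, bp$dbp, beta))
  if (mean_at(beta0) < bp$mbp - tol) {
    abort(sprintf(paste0("calibration-infeasible: mean pressure at beta0 (%.2f mmHg) ",
                         "is below measured mean (%.2f mmHg)"),
                  mean_at(beta0), bp$mbp),
          class = "coawave_error_calibration_infeasible")
  }
  lo <- 1e-6
  hi <- beta0
  iter <- 0L
  while (iter < max_iter && (hi - lo) > 2 * .Machine$double.eps * hi) {
    mid <- (lo + hi) / 2
    if (mean_at(mid) < bp$mbp) lo <- mid else hi <- mid
    iter <- iter + 1L
  }
  beta_star <- (lo + hi) / 2
  p <- synthesize_pressure(cycle, bp$dbp, beta_star)
  err <- abs(cycle_mean(cycle, p) - bp$mbp)
  if (err > tol) {
    abort(sprintf("calibration did not reach tolerance: |mean - mbp| = %.4f mmHg > %g",
                  err, tol),
          class = "coawave_error_calibration")
  }
  structure(list(
    pressure = tibble::tibble(time = cycle$time, pressure = p),
    beta = beta_star, beta0 = beta0, csbp = max(p),
    mean_pressure = cycle_mean(cycle, p), mean_abs_error = err,
    iterations = iter, dbp = bp$dbp, mbp = bp$mbp, sbp = bp$sbp
  ), class = "central_pressure_fit")
}

#' @export
print.central_pressure_fit <- function(x, ...) {
  cat("<central_pressure_fit>\n")
  cat(sprintf("  beta = %.4f (beta0 = %.4f), c-SBP = %.2f mmHg\n",
              x$beta, x$beta0, x$csbp))
  cat(sprintf("  mean pressure %.2f mmHg (target %.2f, |err| %.2g), %d iterations\n",
              x$mean_pressure, x$mbp, x$mean_abs_error, x$iterations))
  invisible(x)
}

#' Tidiers for central pressure fits
#'
#' `tidy()` returns the calibrated parameters as a term/estimate table;
#' `glance()` returns a one-row summary; `augment()`-style access to the
#' synthesized curve is available as `fit$pressure`.
#'
#' @param x A `central_pressure_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.central_pressure_fit <- function(x, ...) {
  tibble::tibble(
    term = c("beta", "csbp", "mean_pressure"),
    estimate = c(x$beta, x$csbp, x$mean_pressure)
  )
}

#' @rdname tidy.central_pressure_fit
#' @export
glance.central_pressure_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, beta0 = x$beta0, csbp = x$csbp,
    mean_pressure = x$mean_pressure, mean_abs_error = x$mean_abs_error,
    iterations = x$iterations
  )
}

#' @rdname tidy.central_pressure_fit
#' @param object A `central_pressure_fit`.
#' @export
autoplot.central_pressure_fit <- function(object, ...) {
  ggplot2::ggplot(object$pressure, ggplot2::aes(x = .data$time, y = .data$pressure)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = c(object$dbp, object$mbp),
                        linetype = c("dashed", "dotted"), colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "synthesized central pressure (mmHg)",
                  title = sprintf("c-SBP %.1f mmHg, beta = %.2f",
                                  object$csbp, object$beta)) +
    ggplot2::theme_minimal()
}
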