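#' Local pulse wave velocity by the Bramwell--Hill relation
#'
#' `c = sqrt(A_d * dP / (rho * dA))` with pressure converted to Pa
#' (1 mmHg = 133.322 Pa) and blood density rho = 1060 kg/m^3. The areas enter
#' only as a ratio so their unit cancels; `dP` must be the central pulse
#' pressure (c-SBP - DBP) and `dA = A_s - A_d` from the same cycle. Being a
#' chord (not tangent) estimate, this is robust to early wave reflections.
#'
#' @param a_d Diastolic area, cm^2.
#' @param delta_a Systolic minus diastolic area, cm^2.
#' @param delta_p Central pulse pressure, mmHg.
#' @return Wave speed in m/s.
#' @examples
#' bramwell_hill_pwv(5, 1, 40) # ~5.02 m/s
#' @export
bramwell_hill_pwv <- function(a_d, delta_a, delta_p) {
  if (!all(is.finite(c(a_d, delta_a, delta_p))) ||
      a_d <= 0 || delta_a <= 0 || delta_p <= 0) {
    abort("a_d, delta_a and delta_p must all be positive",
          class = "coawave_error_pwv")
  }
  sqrt(a_d * delta_p * MMHG_PA / (RHO_SI * delta_a))
}

#' Characteristic impedance of the aortic root
#'
#' `Zc = rho * c / A_d`, evaluated in SI (Pa s/m^3) and converted to
#' mmHg s/mL (divide by 133.322 and by 1e6).
#'
#' @param pwv Local wave speed, m/s.
#' @param a_d Diastolic area, cm^2.
#' @return Characteristic impedance in mmHg s/mL.
#' @examples
#' characteristic_impedance(5, 5) # ~0.0795 mmHg s/mL
#' @export
characteristic_impedance <- function(pwv, a_d) {
  if (!all(is.finite(c(pwv, a_d))) || pwv <= 0 || a_d <= 0) {
    abort("pwv and a_d must be positive", class = "coawave_error_zc")
  }
  zc_si <- RHO_SI * pwv / (a_d * 1e-4)  # Pa s / m^3
  zc_si / MMHG_PA / 1e6
}

#' Stroke volume and cardiac output from the flow curve
#'
#' Stroke volume is the full-cycle integral of flow under the periodic
#' trapezoidal convention ([cycle_integral()]); cardiac output converts to
#' L/min via `SV * (60 / period) / 1000`.
#'
#' @param cycle An [aortic_cycle()].
#' @return A tibble with `stroke_volume` (mL), `cardiac_output` (L/min) and
#'   `heart_rate` (1/min). Zero net flow yields `stroke_volume = 0` with a
#'   warning (cardiac output is then unusable downstream); negative stroke
#'   volume (sign-convention violation) is an error.
#' @export
cardiac_output <- function(cycle) {
  stopifnot(is_aortic_cycle(cycle))
  sv <- cycle_integral(cycle, cycle$flow)
  if (sv < 0) {
    abort(sprintf("negative stroke volume (%.2f mL): flow sign convention violated", sv),
          class = "coawave_error_flow_sign")
  }
  if (sv == 0) {
    warning("zero stroke volume: cardiac output is degenerate", call. = FALSE)
  }
  period <- cycle_period(cycle)
  tibble::tibble(
    stroke_volume = sv,
    cardiac_output = sv * (60 / period) / 1000,
    heart_rate = 60 / period
  )
}

#' Arterial resistance in Woods units
#'
#' `R = mean BP (mmHg) / cardiac output (L/min)`; indexed resistance
#' multiplies by body surface area.
#'
#' @param mbp Mean pressure, mmHg.
#' @param co Cardiac output, L/min (> 0).
#' @param bsa Body surface area, m^2 (optional; `NA` gives `NA` index).
#' @return A tibble with `resistance` (Woods units, mmHg min/L) and
#'   `resistance_indexed` (Woods m^2).
#' @export
arterial_resistance <- function(mbp, co, bsa = NA_real_) {
  if (!is.finite(co) || co <= 0) {
    abort("cardiac output must be positive", class = "coawave_error_resistance")
  }
  r <- mbp / co
  tibble::tibble(resistance = r, resistance_indexed = r * bsa)
}

#' Periodic steady-state pressure of a two-element windkessel
#'
#' Solves `dP/dt = Q(t)/C - P/(R C)` over one cycle with the periodicity
#' condition `P(0) = P(T)` in closed form (integrating factor), using the
#' cycle's flow samples under cyclic extension. Exponentials are arranged so
#' nothing overflows for small time constants.
#'
#' @param cycle An [aortic_cycle()] providing `Q(t)` (mL/s).
#' @param resistance Resistance in Woods units (converted internally with
#'   1 WU = 0.06 mmHg s/mL).
#' @param compliance Compliance `C` in mL/mmHg.
#' @return A tibble `time`, `pressure` (mmHg) aligned with the cycle samples.
#' @export
windkessel_pressure <- function(cycle, resistance, compliance) {
  stopifnot(is_aortic_cycle(cycle))
  if (!all(is.finite(c(resistance, compliance))) || resistance <= 0 ||
      compliance <= 0) {
    abort("resistance and compliance must be positive",
          class = "coawave_error_windkessel")
  }
  r_sml <- resistance * WOODS_TO_MMHG_S_ML  # mmHg s / mL
  tau <- r_sml * compliance
  dt <- cycle_dt(cycle)
  n <- nrow(cycle)
  q <- cycle$flow
  alpha <- exp(-dt / tau)
  # J_k = int_0^{t_k} exp(-(t_k - s)/tau) Q(s) ds, trapezoidal per interval,
  # with the wrap interval (t_{n-1} -> T) using Q wrapped to Q[1].
  seg <- dt / 2 * (alpha * q[-n] + q[-1])
  j <- numeric(n)
  for (k in 2:n) j[k] <- alpha * j[k - 1] + seg[k - 1]
  wrap <- dt / 2 * (alpha * q[n] + q[1])
  j_T <- alpha * j[n] + wrap
  # P0 = J(T) / (C * (1 - exp(-T/tau))), with T = n * dt
  denom <- -expm1(-n * dt / tau)
  p0 <- j_T / (compliance * denom)
  p <- exp(-cycle$time / tau) * p0 + j / compliance
  tibble::tibble(time = cycle$time, pressure = p)
}

#' Total arterial compliance by two-element windkessel tuning
#'
#' Feeds the measured aortic flow curve into a two-element windkessel with
#' the measured arterial resistance and tunes the compliance so that the
#' model's periodic pulse pressure equals the measured pulse pressure. The
#' model pulse pressure is strictly decreasing in `C` (and increasing in
#' `R`), so the tuning is a bisection on `C` in `[1e-3, 1e2]` mL/mmHg with
#' geometric bracket expansion (factor 10, at most 4 times) before declaring
#' the target unreachable. Called with the central pulse pressure
#' (c-SBP - DBP) it yields `TAC_central`; with the brachial pulse pressure,
#' `TAC_brachial`. Only the pulse pressure is matched: the model's absolute
#' pressure level is the periodic solution's own.
#'
#' @param cycle An [aortic_cycle()].
#' @param resistance Resistance in Woods units.
#' @param pulse_pressure Target pulse pressure, mmHg (> 0).
#' @param tol Tolerance on the matched pulse pressure, mmHg (default 0.01).
#' @return Compliance in mL/mmHg (scalar).
#' @export
tac_windkessel <- function(cycle, resistance, pulse_pressure, tol = 0.01) {
  stopifnot(is_aortic_cycle(cycle))
  if (!is.finite(pulse_pressure) || pulse_pressure <= 0) {
    abort("pulse_pressure must be positive", class = "coawave_error_windkessel")
  }
  if (max(cycle$flow) == min(cycle$flow)) {
    abort("target-PP-unreachable: constant flow gives zero model pulse pressure",
          class = "coawave_error_pp_unreachable")
  }
  pp_at <- function(compliance) {
    p <- windkessel_pressure(cycle, resistance, compliance)$pressure
    max(p) - min(p)
  }
  lo <- 1e-3
  hi <- 1e2
  expansions <- 0L
  while (pp_at(lo) < pulse_pressure && expansions < 4L) {
    lo <- lo / 10
    expansions <- expansions + 1L
  }
  if (pp_at(lo) < pulse_pressure) {
    abort(sprintf("target-PP-unreachable: pulse pressure %.2f mmHg exceeds model maximum %.2f mmHg",
                  pulse_pressure, pp_at(lo)),
          class = "coawave_error_pp_unreachable")
  }
  expansions <- 0L
  while (pp_at(hi) > pulse_pressure && expansions < 4L) {
    hi <- hi * 10
    expansions <- expansions + 1L
  }
  if (pp_at(hi) > pulse_pressure) {
    abort("target-PP-unreachable: pulse pressure below the large-compliance limit",
          class = "coawave_error_pp_unreachable")
  }
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (pp_at(mid) > pulse_pressure) lo <- mid else hi <- mid
    if (abs(pp_at(mid) - pulse_pressure) <= tol) break
  }
  mid
}

#' Aortic arch morphology indices
#'
#' Transverse arch index `TI = transverse / descending` (transverse arch
#' hypoplasia) and coarctation index `CI = isthmus / descending`
#' (recoarctation); `CI < 0.7` flags suspected recoarctation. Missing
#' diameters give missing indices rather than an error.
#'
#' @param diam_transverse,diam_isthmus,diam_descending Diameters in mm.
#' @return A tibble with `ti`, `ci`, `recoarctation_suspected`.
#' @examples
#' morphology_indices(20.8, 18.2, 20.0)
#' @export
morphology_indices <- function(diam_transverse, diam_isthmus, diam_descending) {
  for (v in list(diam_transverse, diam_isthmus, diam_descending)) {
    if (!is.na(v) && v <= 0) {
      abort("diameters must be positive when present",
            class = "coawave_error_diameter")
    }
  }
  ti <- if (is.na(diam_transverse) || is.na(diam_descending)) NA_real_ else
    diam_transverse / diam_descending
  ci <- if (is.na(diam_isthmus) || is.na(diam_descending)) NA_real_ else
    diam_isthmus / diam_descending
  tibble::tibble(ti = ti, ci = ci,
                 recoarctation_suspected = !is.na(ci) & ci < 0.7)
}

#' Stiffness and load summary for one subject
#'
#' Convenience wrapper combining [bramwell_hill_pwv()],
#' [characteristic_impedance()], [cardiac_output()],
#' [arterial_resistance()] and [tac_windkessel()] (run twice: central and
#' brachial pulse pressure). Indexed compliances divide by BSA.
#'
#' @param cycle An [aortic_cycle()].
#' @param bp A [brachial_bp()].
#' @param csbp Central systolic pressure, mmHg (from [calibrate_beta()]).
#' @param bsa Body surface area, m^2 (optional).
#' @return One-row tibble with pwv, zc, stroke volume, cardiac output and
#'   index, resistance (raw/indexed), tac_central/tac_brachial
#'   (raw/indexed) and the two pulse pressures.
#' @export
afterload_summary <- function(cycle, bp, csbp, bsa = NA_real_) {
  a_d <- min(cycle$area)
  delta_a <- max(cycle$area) - a_d
  pp_central <- csbp - bp$dbp
  pp_brachial <- bp$sbp - bp$dbp
  pwv <- bramwell_hill_pwv(a_d, delta_a, pp_central)
  zc <- characteristic_impedance(pwv, a_d)
  co <- cardiac_output(cycle)
  res <- arterial_resistance(bp$mbp, co$cardiac_output, bsa)
  tac_c <- tac_windkessel(cycle, res$resistance, pp_central)
  tac_b <- tac_windkessel(cycle, res$resistance, pp_brachial)
  tibble::tibble(
    pwv = pwv, zc = zc,
    stroke_volume = co$stroke_volume, cardiac_output = co$cardiac_output,
    cardiac_index = co$cardiac_output / bsa,
    resistance = res$resistance, resistance_indexed = res$resistance_indexed,
    tac_central = tac_c, tac_brachial = tac_b,
    tac_central_indexed = tac_c / bsa, tac_brachial_indexed = tac_b / bsa,
    pp_central = pp_central, pp_brachial = pp_brachial
  )
}
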