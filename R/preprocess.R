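#' Resample a cycle onto a new uniform grid
#'
#' Linear interpolation of area and flow onto `seq(0, last_time, dt_new)`.
#' Endpoints are preserved; resampling at the native grid spacing is the
#' identity. The new grid must keep at least 16 samples per cycle
#' (`dt_new <= period / 16`).
#'
#' @param cycle An [aortic_cycle()].
#' @param dt_new New sample interval in seconds.
#' @return An [aortic_cycle()] on the new grid.
#' @export
resample_uniform <- function(cycle, dt_new) {
  stopifnot(is_aortic_cycle(cycle))
  period <- cycle_period(cycle)
  if (!is.numeric(dt_new) || length(dt_new) != 1L || dt_new <= 0) {
    abort("dt_new must be a single positive number",
          class = "coawave_error_resample")
  }
  if (dt_new > period / 16) {
    abort(sprintf("dt_new = %g s too coarse: must be <= period/16 = %g s",
                  dt_new, period / 16),
          class = "coawave_error_resample")
  }
  t_old <- cycle$time
  n_new <- floor(t_old[length(t_old)] / dt_new + 1e-9) + 1L
  t_new <- (seq_len(n_new) - 1L) * dt_new
  area <- approx(t_old, cycle$area, xout = t_new, rule = 2)$y
  flow <- approx(t_old, cycle$flow, xout = t_new, rule = 2)$y
  aortic_cycle(tibble::tibble(time = t_new, area = area, flow = flow),
               period = t_new[n_new] + dt_new)
}

#' Savitzky-Golay smoothing of area and flow
#'
#' Polynomial moving-window smoothing (via [signal::sgolayfilt()]) of the
#' area and flow channels; the time grid is unchanged and area positivity is
#' re-checked afterwards. Smoothing is nowhere applied implicitly: the
#' analysis stages operate on the samples they are given.
#'
#' @param cycle An [aortic_cycle()].
#' @param window Odd window length in samples, at least `polyorder + 2`.
#' @param polyorder Polynomial order (default 3).
#' @return A smoothed [aortic_cycle()].
#' @export
smooth_cycle <- function(cycle, window = 9L, polyorder = 3L) {
  stopifnot(is_aortic_cycle(cycle))
  window <- as.integer(window)
  polyorder <- as.integer(polyorder)
  if (window %% 2L == 0L || window < polyorder + 2L) {
    abort(sprintf("window must be odd and >= polyorder + 2 (got window=%d, polyorder=%d)",
                  window, polyorder),
          class = "coawave_error_smooth")
  }
  area <- signal::sgolayfilt(cycle$area, p = polyorder, n = window)
  flow <- signal::sgolayfilt(cycle$flow, p = polyorder, n = window)
  aortic_cycle(tibble::tibble(time = cycle$time, area = area, flow = flow),
               period = cycle_period(cycle))
}

#' Incremental wavefronts of area and flow
#'
#' First differences of the area and flow samples, attributed to interval
#' midpoints. Waves are treated as a summation of these incremental
#' wavefronts; first differences (rather than centred derivatives) keep the
#' increments telescoping exactly: `sum(dA) = area[n] - area[1]`.
#'
#' @param cycle An [aortic_cycle()].
#' @return A tibble with columns `t_mid` (s), `dA` (cm^2) and `dQ` (mL/s),
#'   one row per sample interval (length `n - 1`).
#' @export
increments <- function(cycle) {
  stopifnot(is_aortic_cycle(cycle))
  n <- nrow(cycle)
  tibble::tibble(
    t_mid = (cycle$time[-n] + cycle$time[-1]) / 2,
    dA = diff(cycle$area),
    dQ = diff(cycle$flow)
  )
}
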