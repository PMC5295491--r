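#' Separate area and flow increments into forward and backward components
#'
#' With the local wave speed `c` (converted to cm/s so the units are
#' consistent with cm^2 and mL/s):
#' `dA+- = (dA +- dQ/c)/2` and `dQ+- = (dQ +- c dA)/2`, so that
#' `dQ+ = c dA+` and `dQ- = -c dA-`. Wave intensity is the dt-free
#' incremental product `dI = dA * dQ`, with `dI+- = dA+- * dQ+-`; summation
#' over a wave's support gives its magnitude in cm^5 (the unit convention of
#' noninvasive, area-based wave intensity). By construction
#' `dA+ + dA- = dA`, `dQ+ + dQ- = dQ`, `dI+ + dI- = dI`, `dI+ >= 0` and
#' `dI- <= 0` at every increment.
#'
#' @param incr A tibble of increments from [increments()] (columns `t_mid`,
#'   `dA`, `dQ`).
#' @param pwv Local wave speed in m/s (> 0), typically the Bramwell--Hill
#'   estimate from the same cycle.
#' @return A tibble of class `separated_increments` with columns `t_mid`,
#'   `dA`, `dQ`, `dA_plus`, `dA_minus`, `dQ_plus`, `dQ_minus`, `dI`,
#'   `dI_plus`, `dI_minus`, and attribute `c_cm_s`.
#' @export
separate_waves <- function(incr, pwv) {
  if (!is.data.frame(incr) || !all(c("dA", "dQ") %in% names(incr))) {
    abort("incr must have columns dA and dQ (see increments())",
          class = "coawave_error_column")
  }
  if (!is.finite(pwv) || pwv <= 0) abort("pwv must be positive",
                                         class = "coawave_error_pwv")
  c_cm_s <- pwv * 100
  dA <- incr$dA
  dQ <- incr$dQ
  dA_plus <- (dA + dQ / c_cm_s) / 2
  dA_minus <- (dA - dQ / c_cm_s) / 2
  dQ_plus <- (dQ + c_cm_s * dA) / 2
  dQ_minus <- (dQ - c_cm_s * dA) / 2
  out <- tibble::tibble(
    t_mid = if ("t_mid" %in% names(incr)) incr$t_mid else seq_along(dA),
    dA = dA, dQ = dQ,
    dA_plus = dA_plus, dA_minus = dA_minus,
    dQ_plus = dQ_plus, dQ_minus = dQ_minus,
    dI = dA * dQ,
    dI_plus = dA_plus * dQ_plus,
    dI_minus = dA_minus * dQ_minus
  )
  out <- tibble::new_tibble(out, nrow = nrow(out), class = "separated_increments")
  attr(out, "c_cm_s") <- c_cm_s
  out
}

#' Forward and backward area waveforms
#'
#' Cumulative sums of `dA+` and `dA-` starting at zero; their sum
#' reconstructs `area - area[1]` exactly (telescoping). The amplitudes
#' (max - min) of the two cumulated waveforms feed [reflection_magnitude()].
#'
#' @param separated A `separated_increments` tibble from [separate_waves()].
#' @return A tibble `t_mid`, `A_plus`, `A_minus`.
#' @export
cumulate_area <- function(separated) {
  stopifnot(inherits(separated, "separated_increments"))
  tibble::tibble(
    t_mid = separated$t_mid,
    A_plus = cumsum(separated$dA_plus),
    A_minus = cumsum(separated$dA_minus)
  )
}

#' Reflection magnitude
#'
#' Amplitude ratio of the backward to the forward separated area waveform,
#' `amplitude(A_minus) / amplitude(A_plus)` with amplitude = max - min.
#'
#' @param a_plus,a_minus Cumulated forward/backward area waveforms (numeric
#'   vectors, e.g. the columns of [cumulate_area()]).
#' @return Dimensionless ratio (>= 0).
#' @export
reflection_magnitude <- function(a_plus, a_minus) {
  amp_f <- max(a_plus) - min(a_plus)
  if (amp_f <= 0) {
    abort("flat forward area waveform: separation failure",
          class = "coawave_error_separation")
  }
  (max(a_minus) - min(a_minus)) / amp_f
}

#' Detect and classify waves in the separated intensity traces
#'
#' Waves are maximal contiguous runs of increments where the separated
#' intensity exceeds (in absolute value) `min_peak_fraction` times its own
#' channel's peak. Forward waves come from `dI+` and are compression (FCW)
#' when the run-integral of `dA+` is positive, expansion (FEW) otherwise;
#' backward waves come from `dI-` and are compression (BCW) when the
#' run-integral of `dA-` is positive (area rising while flow decelerates),
#' expansion (BEW) otherwise. Magnitude is the absolute sum of the separated
#' intensity over the run (numeric integration of the area under the wave);
#' `t_peak` is the increment of largest absolute intensity.
#'
#' A channel whose peak intensity is below `floor_fraction` of the overall
#' intensity peak is treated as empty: a numerically perfect forward wave
#' leaves only rounding residue (~1e-16 relative) in the backward channel,
#' which must not be reported as a wave.
#'
#' @param separated A `separated_increments` from [separate_waves()].
#' @param min_peak_fraction Support threshold as a fraction of the channel
#'   peak (default 0.05).
#' @param floor_fraction Machine-noise floor relative to the overall peak
#'   intensity (default 1e-10).
#' @return A tibble with `kind` (FCW/FEW/BCW/BEW), `t_onset`, `t_peak`,
#'   `t_end`, `magnitude` (cm^5) and `peak_intensity` (cm^5); zero rows when
#'   no wave exceeds threshold.
#' @export
detect_waves <- function(separated, min_peak_fraction = 0.05,
                         floor_fraction = 1e-10) {
  stopifnot(inherits(separated, "separated_increments"))
  overall_peak <- max(abs(separated$dI_plus), abs(separated$dI_minus))
  one_channel <- function(intensity, d_area, forward) {
    peak <- max(abs(intensity))
    if (peak <= floor_fraction * overall_peak) return(NULL)
    active <- abs(intensity) > min_peak_fraction * peak
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    if (!length(keep)) return(NULL)
    purrr::map_dfr(keep, function(k) {
      idx <- starts[k]:ends[k]
      compress <- sum(d_area[idx]) > 0
      kind <- if (forward) {
        if (compress) "FCW" else "FEW"
      } else {
        if (compress) "BCW" else "BEW"
      }
      pk <- idx[which.max(abs(intensity[idx]))]
      tibble::tibble(
        kind = kind,
        t_onset = separated$t_mid[idx[1]],
        t_peak = separated$t_mid[pk],
        t_end = separated$t_mid[idx[length(idx)]],
        magnitude = abs(sum(intensity[idx])),
        peak_intensity = max(abs(intensity[idx]))
      )
    })
  }
  out <- dplyr::bind_rows(
    one_channel(separated$dI_plus, separated$dA_plus, forward = TRUE),
    one_channel(separated$dI_minus, separated$dA_minus, forward = FALSE)
  )
  if (is.null(out) || !nrow(out)) {
    return(tibble::tibble(kind = character(), t_onset = double(),
                          t_peak = double(), t_end = double(),
                          magnitude = double(), peak_intensity = double()))
  }
  dplyr::arrange(out, .data$t_onset)
}

#' Backward compression wave summary
#'
#' Selects the largest-magnitude BCW whose peak lies within systole (the
#' window where flow exceeds `flow_fraction` of its peak) and reports its
#' magnitude and arrival time (time of peak backward intensity). Returns
#' magnitude 0 and `NA` time when no BCW is present.
#'
#' @param waves Wave table from [detect_waves()].
#' @param cycle Optional [aortic_cycle()] used for the systolic gate; when
#'   omitted no gating is applied.
#' @param flow_fraction Systole gate threshold as a fraction of peak flow
#'   (default 0.05).
#' @return A one-row tibble `bcw_magnitude` (cm^5), `bcw_time` (s).
#' @export
bcw_summary <- function(waves, cycle = NULL, flow_fraction = 0.05) {
  bcw <- waves[waves$kind == "BCW", , drop = FALSE]
  if (!is.null(cycle) && nrow(bcw)) {
    thr <- flow_fraction * max(cycle$flow)
    sys_idx <- which(cycle$flow > thr)
    if (length(sys_idx)) {
      t_lo <- cycle$time[min(sys_idx)]
      t_hi <- cycle$time[max(sys_idx)]
      bcw <- bcw[bcw$t_peak >= t_lo & bcw$t_peak <= t_hi, , drop = FALSE]
    }
  }
  if (!nrow(bcw)) {
    return(tibble::tibble(bcw_magnitude = 0, bcw_time = NA_real_))
  }
  top <- bcw[which.max(bcw$magnitude), ]
  tibble::tibble(bcw_magnitude = top$magnitude, bcw_time = top$t_peak)
}

#' Full wave intensity analysis of one cycle
#'
#' Runs [increments()], [separate_waves()], [cumulate_area()],
#' [detect_waves()] and the BCW/reflection summaries in one call.
#'
#' @param cycle An [aortic_cycle()].
#' @param pwv Local wave speed in m/s.
#' @param min_peak_fraction Wave-support threshold (see [detect_waves()]).
#' @param flow_fraction Systole gate for the BCW summary (see
#'   [bcw_summary()]).
#' @return An object of class `wave_analysis`: list with `separated`,
#'   `area_components`, `waves`, `reflection_magnitude`, `bcw_magnitude`,
#'   `bcw_time`, `fcw_magnitude`, `few_magnitude`,
#'   `area_forward_amplitude`, `area_backward_amplitude`, `pwv`.
#' @export
wave_analysis <- function(cycle, pwv, min_peak_fraction = 0.05,
                          flow_fraction = 0.05) {
  stopifnot(is_aortic_cycle(cycle))
  sep <- separate_waves(increments(cycle), pwv)
  comp <- cumulate_area(sep)
  waves <- detect_waves(sep, min_peak_fraction)
  bcw <- bcw_summary(waves, cycle, flow_fraction)
  amp_f <- max(comp$A_plus) - min(comp$A_plus)
  amp_b <- max(comp$A_minus) - min(comp$A_minus)
  mag_of <- function(kind) {
    w <- waves[waves$kind == kind, ]
    if (nrow(w)) max(w$magnitude) else 0
  }
  structure(list(
    separated = sep, area_components = comp, waves = waves,
    reflection_magnitude = if (amp_f > 0) amp_b / amp_f else NA_real_,
    bcw_magnitude = bcw$bcw_magnitude, bcw_time = bcw$bcw_time,
    fcw_magnitude = mag_of("FCW"), few_magnitude = mag_of("FEW"),
    area_forward_amplitude = amp_f, area_backward_amplitude = amp_b,
    pwv = pwv
  ), class = "wave_analysis")
}

#' @export
print.wave_analysis <- function(x, ...) {
  cat("<wave_analysis>\n")
  cat(sprintf("  %d wave(s); FCW %.4g, FEW %.4g, BCW %.4g cm^5%s\n",
              nrow(x$waves), x$fcw_magnitude, x$few_magnitude, x$bcw_magnitude,
              if (is.na(x$bcw_time)) "" else sprintf(" (arrival %.0f ms)",
                                                     1000 * x$bcw_time)))
  cat(sprintf("  reflection magnitude %.3f (pwv %.2f m/s)\n",
              x$reflection_magnitude, x$pwv))
  invisible(x)
}

#' Tidiers for wave analyses
#'
#' `tidy()` returns the detected-wave table; `glance()` a one-row summary of
#' magnitudes, timing and reflection magnitude.
#'
#' @param x A `wave_analysis`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.wave_analysis <- function(x, ...) x$waves

#' @rdname tidy.wave_analysis
#' @export
glance.wave_analysis <- function(x, ...) {
  tibble::tibble(
    fcw_magnitude = x$fcw_magnitude, few_magnitude = x$few_magnitude,
    bcw_magnitude = x$bcw_magnitude, bcw_time = x$bcw_time,
    reflection_magnitude = x$reflection_magnitude,
    area_forward_amplitude = x$area_forward_amplitude,
    area_backward_amplitude = x$area_backward_amplitude,
    n_waves = nrow(x$waves), pwv = x$pwv
  )
}

#' @rdname tidy.wave_analysis
#' @param object A `wave_analysis`.
#' @export
autoplot.wave_analysis <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$separated[, c("t_mid", "dI_plus", "dI_minus")],
    cols = c("dI_plus", "dI_minus"),
    names_to = "channel", values_to = "intensity"
  )
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$t_mid, y = .data$intensity,
                                         colour = .data$channel)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::scale_colour_manual(values = c(dI_plus = "#00557f",
                                            dI_minus = "#b2182b"),
                                 labels = c(dI_plus = "dI+", dI_minus = "dI-")) +
    ggplot2::labs(x = "time (s)", y = "wave intensity (cm^5 per increment)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$waves)) {
    gg <- gg + ggplot2::geom_vline(
      data = object$waves,
      mapping = ggplot2::aes(xintercept = .data$t_peak),
      linetype = "dotted", colour = "grey40"
    )
  }
  gg
}
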