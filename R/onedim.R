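#' One-dimensional pulse-wave network
#'
#' A reduced model of the aorta: an ordered chain of linearly tapered,
#' compliant segments (linear-elastic tube law
#' `A(p) = A_ref (1 + D (p - p_ref))` with distensibility `D` in 1/mmHg),
#' driven by a time-varying elastance ventricle through an aortic valve,
#' with head-and-arm vessels lumped into a side windkessel at an internal
#' junction and the descending aorta ending in a three-element windkessel.
#' The solver integrates the 1D mass/momentum equations with Poiseuille
#' friction (two-step explicit predictor--corrector, characteristic-based
#' boundary coupling) until the root pressure is cycle-to-cycle periodic.
#'
#' @param length Segment length, cm.
#' @param inlet_diameter,outlet_diameter Diameters, cm (linear taper).
#' @param distensibility Relative area change per mmHg (1/mmHg).
#' @param n_nodes Grid nodes for the segment (>= 8).
#' @param name Optional segment name.
#' @return `one_d_segment()` returns a one-row tibble.
#' @export
one_d_segment <- function(length, inlet_diameter, outlet_diameter,
                          distensibility, n_nodes, name = NA_character_) {
  if (any(c(length, inlet_diameter, outlet_diameter, distensibility) <= 0)) {
    abort("segment geometry and distensibility must be positive",
          class = "coawave_error_network")
  }
  n_nodes <- as.integer(n_nodes)
  if (n_nodes < 8L) abort("n_nodes must be >= 8", class = "coawave_error_network")
  tibble::tibble(name = name, length = length,
                 inlet_diameter = inlet_diameter,
                 outlet_diameter = outlet_diameter,
                 distensibility = distensibility, n_nodes = n_nodes)
}

#' @rdname one_d_segment
#' @param segments Tibble of segments (rows root to descending aorta), e.g.
#'   from [one_d_segment()] stacked with `dplyr::bind_rows()`.
#' @param heart List with `Emax_mmHg_ml`, `Emin_mmHg_ml`, `V0_ml`,
#'   `p_fill_mmHg`, `Rmv_mmHg_s_ml`, `Rav_mmHg_s_ml`, `t_rise_s`, `t_fall_s`.
#' @param junction_terminals List of length `nrow(segments) - 1`: `NULL` or
#'   a list `R1_mmHg_s_ml`, `R2_mmHg_s_ml`, `C_ml_mmHg`, `p_ven_mmHg` for a
#'   lumped side outflow at that junction (set `C_ml_mmHg = 0` for a pure
#'   resistor).
#' @param terminal Distal windkessel, same fields as a junction terminal.
#' @param cycle_period Cycle length, s.
#' @param p_ref Tube-law reference pressure, mmHg.
#' @param p_init Initial pressure everywhere (tube and capacitors), mmHg;
#'   starting near the expected working pressure shortens the transient.
#' @return `one_d_network()` returns a list of class `one_d_network`.
#' @export
one_d_network <- function(segments, heart, junction_terminals, terminal,
                          cycle_period = 0.85, p_ref = 72, p_init = p_ref) {
  stopifnot(is.data.frame(segments), nrow(segments) >= 1)
  if (length(junction_terminals) != nrow(segments) - 1) {
    abort("junction_terminals must have one entry per internal junction",
          class = "coawave_error_network")
  }
  structure(list(segments = tibble::as_tibble(segments), heart = heart,
                 junction_terminals = junction_terminals, terminal = terminal,
                 cycle_period = cycle_period, p_ref = p_ref, p_init = p_init,
                 rho = RHO_SI, mu_poise = 0.04),
            class = "one_d_network")
}

#' Packaged default aorta network
#'
#' Reads the default network description shipped with the package (a JSON
#' file under `extdata`, user-overridable via `path`).
#'
#' @param path Optional path to a JSON network description with the same
#'   structure as the packaged default.
#' @return A `one_d_network`.
#' @export
default_aorta_network <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aorta_network_default.json",
                        package = "coawave")
  }
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  segs <- purrr::map_dfr(cfg$segments, function(s) {
    one_d_segment(s$length_cm, s$inlet_diameter_cm, s$outlet_diameter_cm,
                  s$distensibility_per_mmHg, s$n_nodes, s$name)
  })
  net <- one_d_network(
    segments = segs, heart = cfg$heart,
    junction_terminals = cfg$junction_terminals,
    terminal = cfg$terminal,
    cycle_period = cfg$cycle_period_s, p_ref = cfg$p_ref_mmHg,
    p_init = if (is.null(cfg$p_init_mmHg)) cfg$p_ref_mmHg else cfg$p_init_mmHg
  )
  net
}

#' Coarctation scenario specification
#'
#' Three scenarios: `baseline` (packaged defaults), `narrow` (target-segment
#' diameters reduced by `narrowing_fraction`, distensibility unchanged —
#' a mild residual coarctation) and `narrow_stiff` (the narrowed segment
#' additionally stiffened by dividing its distensibility by
#' `stiffness_multiplier`, emulating a fibrous repair-site scar).
#'
#' @param name `"baseline"`, `"narrow"` or `"narrow_stiff"`.
#' @param narrowing_fraction Diameter reduction in `[0, 0.9]` (default 0.25).
#' @param stiffness_multiplier Distensibility divisor for `narrow_stiff`
#'   (default 1e5).
#' @param target_segment Index of the modified segment (default 4, the
#'   isthmus).
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(name = c("baseline", "narrow", "narrow_stiff"),
                          narrowing_fraction = 0.25,
                          stiffness_multiplier = 1e5,
                          target_segment = 4L) {
  name <- match.arg(name)
  if (narrowing_fraction < 0 || narrowing_fraction > 0.9) {
    abort("narrowing_fraction must lie in [0, 0.9]",
          class = "coawave_error_network")
  }
  structure(list(name = name, narrowing_fraction = narrowing_fraction,
                 stiffness_multiplier = stiffness_multiplier,
                 target_segment = as.integer(target_segment)),
            class = "scenario_spec")
}

#' @rdname scenario_spec
#' @param spec A `scenario_spec`.
#' @param network Base network (default [default_aorta_network()]).
#' @return `build_scenario()` returns the modified `one_d_network`.
#' @export
build_scenario <- function(spec, network = default_aorta_network()) {
  stopifnot(inherits(spec, "scenario_spec"), inherits(network, "one_d_network"))
  if (spec$name == "baseline") return(network)
  i <- spec$target_segment
  if (i < 1 || i > nrow(network$segments)) {
    abort("target_segment out of range", class = "coawave_error_network")
  }
  keep <- 1 - spec$narrowing_fraction
  network$segments$inlet_diameter[i] <- network$segments$inlet_diameter[i] * keep
  network$segments$outlet_diameter[i] <- network$segments$outlet_diameter[i] * keep
  if (spec$name == "narrow_stiff") {
    network$segments$distensibility[i] <-
      network$segments$distensibility[i] / spec$stiffness_multiplier
  }
  network
}

wk_cgs <- function(x, p_ref) {
  if (is.null(x)) return(NULL)
  list(R1 = x$R1_mmHg_s_ml * MMHG_CGS, R2 = x$R2_mmHg_s_ml * MMHG_CGS,
       C = x$C_ml_mmHg / MMHG_CGS, p_ven = x$p_ven_mmHg * MMHG_CGS)
}

#' Run the 1D pulse-wave simulation
#'
#' Integrates the network to periodic steady state (root-pressure
#' cycle-to-cycle change below `periodicity_tol`, or `n_cycles_max` cycles
#' with a warning flag) and returns the final cycle at the root node,
#' resampled to the standard 9.6 ms grid.
#'
#' @param network A `one_d_network`.
#' @param n_cycles_max Maximum number of cardiac cycles (default 20).
#' @param periodicity_tol Max-norm root-pressure periodicity tolerance, mmHg
#'   (default 0.5).
#' @param refine Integer grid-refinement factor (multiplies every segment's
#'   node count; used for grid-convergence checks).
#' @param dt_out Output sampling interval for the stored root trace, s.
#' @param dt_std Grid for the returned [aortic_cycle()] (default 0.0096 s).
#' @return A list of class `onedim_result`: `cycle` (root [aortic_cycle()]
#'   on the standard grid), `trace` (tibble `time`, `area`, `flow`,
#'   `pressure` at `dt_out`), `converged`, `n_cycles`, `max_cycle_dp`,
#'   `mass_balance` (volumes in mL and relative errors), `dt`.
#' @export
simulate_network <- function(network, n_cycles_max = 20L,
                             periodicity_tol = 0.5, refine = 1L,
                             dt_out = 0.002, dt_std = 0.0096) {
  stopifnot(inherits(network, "one_d_network"))
  segs <- network$segments
  p_ref_cgs <- network$p_ref * MMHG_CGS
  seg_list <- purrr::pmap(segs, function(name, length, inlet_diameter,
                                         outlet_diameter, distensibility,
                                         n_nodes, ...) {
    n <- as.integer(n_nodes) * as.integer(refine)
    d <- seq(inlet_diameter, outlet_diameter, length.out = n)
    list(n = n, dx = length / (n - 1),
         K = MMHG_CGS / distensibility,
         Aref = pi * d^2 / 4)
  })
  # stability: dt from the stiffest segment's wave speed, with a per-segment
  # distension margin from the tube law (a nearly rigid segment barely
  # distends, so its wave speed needs almost no headroom). Compliant
  # segments take a tighter Courant bound (0.42) so their boundary
  # half-cells, whose conservative update doubles the effective Courant
  # number, stay stable and conservative; quasi-rigid segments (which store
  # no volume and fall back to characteristic boundary states) may run up
  # to 0.85.
  c_ref <- vapply(seg_list, function(s) sqrt(s$K / RHO_CGS), numeric(1))
  distens <- segs$distensibility
  margin <- sqrt(1 + pmax(0, distens * (170 - network$p_ref)))
  courant <- ifelse(distens < 1e-5, 0.85, 0.42)
  dx <- vapply(seg_list, `[[`, numeric(1), "dx")
  dt <- min(courant * dx / (margin * c_ref + 300), 2e-4)

  heart <- network$heart
  heart_cgs <- list(
    Emax = heart$Emax_mmHg_ml * MMHG_CGS, Emin = heart$Emin_mmHg_ml * MMHG_CGS,
    V0 = heart$V0_ml, p_fill = heart$p_fill_mmHg * MMHG_CGS,
    Rmv = heart$Rmv_mmHg_s_ml * MMHG_CGS, Rav = heart$Rav_mmHg_s_ml * MMHG_CGS,
    t_rise = heart$t_rise_s, t_fall = heart$t_fall_s
  )
  junctions <- purrr::map(network$junction_terminals, wk_cgs,
                          p_ref = network$p_ref)
  terminal <- wk_cgs(network$terminal, network$p_ref)
  out_every <- max(1L, floor(dt_out / dt))

  res <- onedim_simulate_cpp(
    seg_list, junctions, terminal, heart_cgs,
    rho = RHO_CGS, mu = network$mu_poise,
    p_ref = p_ref_cgs, p_init = network$p_init * MMHG_CGS,
    dt = dt, period = network$cycle_period,
    n_cycles_max = as.integer(n_cycles_max),
    periodicity_tol = periodicity_tol * MMHG_CGS,
    out_every = out_every
  )
  if (!res$converged) {
    warning(sprintf(
      "1D simulation not periodic after %d cycles (last cycle-to-cycle change %.3f mmHg); returning last cycle",
      res$n_cycles, res$max_cycle_dp / MMHG_CGS), call. = FALSE)
  }
  trace <- tibble::tibble(
    time = res$time, area = res$area, flow = res$flow,
    pressure = res$pressure / MMHG_CGS
  )
  n_std <- floor(network$cycle_period / dt_std)
  t_std <- (seq_len(n_std) - 1) * dt_std
  interp <- function(y) approx(trace$time, y, xout = t_std, rule = 2)$y
  cycle <- aortic_cycle(tibble::tibble(
    time = t_std, area = interp(trace$area), flow = interp(trace$flow)
  ))
  raw_err <- abs(res$vol_in - res$vol_out) / res$vol_in
  closed_err <- abs(res$vol_in - res$vol_out - res$storage_delta) / res$vol_in
  structure(list(
    cycle = cycle, trace = trace,
    pressure_std = interp(trace$pressure),
    converged = res$converged, n_cycles = res$n_cycles,
    max_cycle_dp = res$max_cycle_dp / MMHG_CGS,
    conv_history = res$conv_history / MMHG_CGS,
    mass_balance = list(vol_in = res$vol_in, vol_out = res$vol_out,
                        storage_delta = res$storage_delta,
                        relative_error = raw_err,
                        relative_error_closed = closed_err),
    dt = res$dt, network = network
  ), class = "onedim_result")
}

#' @export
print.onedim_result <- function(x, ...) {
  p <- x$trace$pressure
  cat("<onedim_result>\n")
  cat(sprintf("  root pressure %.0f/%.0f mmHg, %d cycle(s), %s (dp %.3g mmHg)\n",
              max(p), min(p), x$n_cycles,
              if (x$converged) "periodic" else "NOT periodic", x$max_cycle_dp))
  cat(sprintf("  mass balance: in %.1f mL, out %.1f mL (raw error %.2f%%)\n",
              x$mass_balance$vol_in, x$mass_balance$vol_out,
              100 * x$mass_balance$relative_error))
  invisible(x)
}

#' @rdname simulate_network
#' @param object An `onedim_result`.
#' @param ... Unused.
#' @export
autoplot.onedim_result <- function(object, ...) {
  df <- tidyr::pivot_longer(object$trace, cols = c("pressure", "flow", "area"),
                            names_to = "channel", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.6, colour = "#00557f") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(c(
                          pressure = "pressure (mmHg)", flow = "flow (mL/s)",
                          area = "area (cm2)"))) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Wave intensity analysis of a simulated scenario
#'
#' Runs [build_scenario()], [simulate_network()] and the same
#' [wave_analysis()] used for in-vivo subjects on the root cycle, with the
#' wave speed taken from the Bramwell--Hill estimate on the simulated root
#' waveforms (pulse pressure from the simulated pressure itself).
#'
#' @param spec A [scenario_spec()].
#' @param network Base network.
#' @param ... Passed to [simulate_network()].
#' @return A list with `spec`, `simulation` (the `onedim_result`), `pwv`
#'   (m/s) and `wia` (a [wave_analysis()] object).
#' @export
scenario_wia <- function(spec, network = default_aorta_network(), ...) {
  sim <- simulate_network(build_scenario(spec, network), ...)
  a_d <- min(sim$cycle$area)
  delta_a <- max(sim$cycle$area) - a_d
  delta_p <- max(sim$pressure_std) - min(sim$pressure_std)
  pwv <- bramwell_hill_pwv(a_d, delta_a, delta_p)
  list(spec = spec, simulation = sim, pwv = pwv,
       wia = wave_analysis(sim$cycle, pwv))
}

#' Idealized uniform tube with a matched terminal load
#'
#' A single untapered segment terminated by a pure resistance equal to its
#' characteristic impedance (`Zc = rho c / A`), i.e. a reflectionless load:
#' transmission-line theory then predicts essentially no backward wave at
#' the root, which is the solver's reflection-free validation case. The
#' default heart parameters drive a deliberately small pulse (a few mmHg):
#' the matched-load argument is a small-signal (linear) limit, and at
#' physiological pulse amplitudes the area-dependence of the wave speed
#' itself produces an apparent reflection of order 10%.
#'
#' @param length Tube length, cm.
#' @param diameter Diameter, cm.
#' @param distensibility 1/mmHg.
#' @param n_nodes Grid nodes.
#' @param cycle_period Cycle length, s.
#' @param p_ref Reference pressure, mmHg (also the terminal back-pressure).
#' @return A `one_d_network`.
#' @export
uniform_tube_network <- function(length = 40, diameter = 2.2,
                                 distensibility = 5e-3, n_nodes = 64,
                                 cycle_period = 0.85, p_ref = 72) {
  a <- pi * diameter^2 / 4
  c_cgs <- sqrt(MMHG_CGS / (RHO_CGS * distensibility))
  zc_mmhg_s_ml <- RHO_CGS * c_cgs / a / MMHG_CGS
  seg <- one_d_segment(length, diameter, diameter, distensibility, n_nodes,
                       name = "uniform_tube")
  one_d_network(
    segments = seg,
    heart = list(Emax_mmHg_ml = 1.0, Emin_mmHg_ml = 0.05, V0_ml = 10,
                 p_fill_mmHg = 4, Rmv_mmHg_s_ml = 0.01,
                 Rav_mmHg_s_ml = 0.05, t_rise_s = 0.30, t_fall_s = 0.45),
    junction_terminals = list(),
    terminal = list(R1_mmHg_s_ml = zc_mmhg_s_ml, R2_mmHg_s_ml = 1,
                    C_ml_mmHg = 0, p_ven_mmHg = p_ref),
    cycle_period = cycle_period, p_ref = p_ref
  )
}
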