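# Deterministic analytic fixtures used across the suite.

# A smooth, pulsatile single cycle: sin^2 ejection flow and an area waveform
# rising with the flow (not tied to any tube law unless stated).
make_cycle <- function(n = 90, dt = 0.0096, a_d = 5, pulse_area = 0.8,
                       q_peak = 400, onset = 0.04, t_ej = 0.3) {
  t <- (seq_len(n) - 1) * dt
  s <- pmin(pmax((t - onset) / t_ej, 0), 1)
  shape <- sin(pi * s)^2
  aortic_cycle(tibble::tibble(
    time = t,
    area = a_d + pulse_area * shape,
    flow = q_peak * shape
  ))
}

# Zero-noise cohort parameters for closed-loop recovery tests.
noiseless_params <- function(...) {
  cohort_params(noise_sd_area = 0, noise_sd_flow = 0, ...)
}

# A pure-forward (no backward wave) parameter set.
pure_forward_params <- function(...) {
  noiseless_params(
    bcw_magnitude = list(patient = list(meanlog = -Inf, sdlog = 0),
                         control = list(meanlog = -Inf, sdlog = 0)),
    ...
  )
}
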