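# Independent oracles. These deliberately avoid the package's own closed-form
# or bisection code paths.

# Brute-force two-element windkessel: RK4 time stepping of
# dP/dt = Q(t)/C - P/(R C) from an arbitrary start until the cycle-to-cycle
# pressure change is negligible; returns the periodic pulse pressure.
wk_pp_ode <- function(cycle, resistance_wu, compliance, substeps = 30,
                      max_cycles = 400, tol = 1e-10) {
  r_sml <- resistance_wu * 0.06
  tau <- r_sml * compliance
  dt <- cycle_dt(cycle)
  n <- nrow(cycle)
  qfun <- function(tt) {
    tt <- tt %% (n * dt)
    i <- tt / dt
    i0 <- floor(i)
    w <- i - i0
    q0 <- cycle$flow[(i0 %% n) + 1]
    q1 <- cycle$flow[((i0 + 1) %% n) + 1]
    (1 - w) * q0 + w * q1
  }
  deriv <- function(tt, p) qfun(tt) / compliance - p / tau
  h <- dt / substeps
  p <- 0
  trace <- numeric(n)
  prev <- NULL
  for (cyc in seq_len(max_cycles)) {
    for (k in seq_len(n)) {
      trace[k] <- p
      t0 <- (k - 1) * dt
      for (j in seq_len(substeps)) {
        tt <- t0 + (j - 1) * h
        k1 <- deriv(tt, p)
        k2 <- deriv(tt + h / 2, p + h / 2 * k1)
        k3 <- deriv(tt + h / 2, p + h / 2 * k2)
        k4 <- deriv(tt + h, p + h * k3)
        p <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
    }
    if (!is.null(prev) && max(abs(trace - prev)) < tol) break
    prev <- trace
  }
  max(trace) - min(trace)
}

# Dense grid search over the pressure-area scaling factor: the oracle for
# the bisection calibration.
grid_search_beta <- function(cycle, bp, n_grid = 1e4) {
  beta0 <- initial_beta(cycle, bp)
  betas <- seq(1e-6, beta0, length.out = n_grid)
  a_rel <- cycle$area / min(cycle$area) - 1
  means <- vapply(betas, function(b) mean(bp$dbp * exp(b * a_rel)), numeric(1))
  betas[which.min(abs(means - bp$mbp))]
}
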