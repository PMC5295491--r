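---
title: "Methods: central hemodynamics and wave intensity after coarctation repair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: central hemodynamics and wave intensity after coarctation repair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coawave)
```

## The problem

After surgical repair of aortic coarctation, the conduit arteries are often
abnormal even when cuff pressure is not: the repair site is stiff fibrous
tissue, the ascending aorta remodels, and reflected pressure waves return
early and enlarged. Because brachial-to-aortic pulse amplification hides
part of this burden from the cuff, the analysis has to work at the aortic
root. `coawave` takes, per subject, one cardiac cycle of aortic
cross-sectional area `A(t)` (cm²) and flow `Q(t)` (mL/s) sampled uniformly
(9.6 ms in the intended acquisitions, any uniform grid accepted) plus an
oscillometric brachial systolic/diastolic/mean pressure, and derives central
systolic pressure, stiffness, lumped afterload, and separated wave
intensity.

## Central pressure calibration

The exponential pressure–area law
`p(t) = p_d exp(β (A(t)/A_d − 1))`
is anchored at the brachial diastolic pressure `p_d` and diastolic area
`A_d`. Two conventions are fixed here because the method leaves them open:

* `A_d` is the global minimum of the sampled area (earliest sample on
  ties). No sub-sample interpolation is attempted.
* the "mean of the synthesized curve" is the time average over the full
  acquired cycle under cyclic extension; on a uniform grid the periodic
  trapezoidal average equals the plain arithmetic mean, which is what
  `cycle_mean()` computes. The generator uses the same functional, so
  closed-loop recovery is exact rather than approximate.

The calibration starts from the theoretical maximum
`β₀ = ln(SBP/DBP)·A_d/(A_s − A_d)` (synthesized peak = brachial SBP; central
systolic pressure cannot exceed brachial) and reduces β by bisection on
`[10⁻⁶, β₀]` until the synthesized mean matches the measured brachial mean.
The mean is strictly increasing in β — the exponential is increasing and
the area ratio is non-negative — so bisection is exact; the bracket is
shrunk to machine precision (about 52 iterations) and the result accepted
when the mean-pressure residual is below `tol` (default 0.01 mmHg). The
residual tolerance is expressed in pressure, not in β, because pressure is
the quantity with a meaningful scale. `calibrate_beta()` refuses
impossible inputs explicitly: a flat area waveform (`β₀` undefined) and a
measured mean above the reachable maximum (inconsistent cuff/area data).

The measured oscillometric mean is used as-is. A form-factor fallback
(`mbp = dbp + PP/3`) exists as `estimate_mbp()` but is never applied
implicitly.

## Stiffness, impedance, resistance, compliance

* Bramwell–Hill wave speed `c = √(A_d ΔP/(ρ ΔA))`, with ρ = 1060 kg/m³,
  `ΔA = A_s − A_d`, and `ΔP` strictly the central pulse pressure
  (c-SBP − DBP) from the calibrated curve. As a chord estimate it is robust
  to early reflections, unlike single-site loop methods.
* Characteristic impedance `Z_c = ρc/A_d`, reported in mmHg·s/mL
  (1 mmHg = 133.322 Pa).
* Stroke volume is the periodic trapezoidal flow integral (`dt·ΣQ` on the
  uniform grid); resistance `R = MAP/CO` in Woods units
  (1 WU = 0.06 mmHg·s/mL), indexed by multiplying with BSA.
* Total arterial compliance: the two-element windkessel
  `dP/dt = Q(t)/C − P/(RC)` is solved in closed form for its periodic
  steady state (integrating factor plus periodicity condition, arranged so
  no exponential overflows at small time constants), and `C` is tuned by
  bisection until the model pulse pressure equals the measured one. The
  model pulse pressure is strictly decreasing in `C`, so the tuning is
  well-posed; the bracket `[10⁻³, 10²]` mL/mmHg expands geometrically (×10,
  at most 4 times) before the target is declared unreachable. Only the
  pulse pressure is matched — the model's absolute level is left free,
  since the tuning uses no diastolic anchor. Run with central pulse
  pressure it yields `TAC_central`, with brachial `TAC_brachial`; indexed
  values divide by BSA. An independent transient RK4 time-stepper verifies
  the closed form in the test suite (they agree within 0.5%); it is never
  used in the analysis path.

## Wave intensity analysis

Waves are treated as summed incremental wavefronts: first differences
`dA, dQ` at interval midpoints (not centred derivatives), so the increments
telescope exactly. With the Bramwell–Hill speed `c` (cm/s):

```
dA± = (dA ± dQ/c)/2      dQ± = (dQ ± c·dA)/2      dI = dA·dQ,  dI± = dA±·dQ±
```

These satisfy, by algebra that the tests verify to 1e-12: the ± components
sum to the originals, `dQ± = ±c·dA±`, `dI₊ ≥ 0 ≥ dI₋`, and
`dI₊ + dI₋ = dI` (the cross terms cancel). Wave intensity is deliberately
the dt-free incremental product, so magnitudes integrate to cm⁵ — the unit
convention of noninvasive area-based WIA — rather than the W/m² of
pressure–velocity WIA.

Wave detection conventions (the method itself states none, so they are
config-exposed with these defaults):

* a wave is a maximal contiguous run of increments with `|dI±|` above 5% of
  its channel's peak (`min_peak_fraction`);
* a channel whose peak is below 1e-10 of the overall intensity peak is
  empty — numerically pure forward waves must not report rounding residue
  as backward waves;
* forward waves are compression (FCW) when the run-integral of `dA₊` is
  positive, expansion (FEW) otherwise; backward waves likewise from `dA₋`
  (BCW: area rising while flow decelerates);
* the backward compression wave reported per subject is the
  largest-magnitude BCW whose peak lies in systole (flow above 5% of its
  peak), and its arrival is the time of peak `|dI₋|` — the peak is robust
  to the support threshold, an onset is not;
* the reflection magnitude is `amplitude(A₋)/amplitude(A₊)` of the
  cumulated (integrated) separated area waveforms, amplitude = max − min.

## The synthetic cohort

No subject-level data ships with the method, so the generator is the test
bed: it constructs subjects in the separated (±) domain, where ground truth
is exact by construction, and sums them. Per subject:

1. An asymmetric ejection template (squared-sine rise to 30% of the
   ejection window, squared-cosine decay; window 37% of the cycle starting
   40 ms after the R-wave) is scaled to the drawn stroke volume. The fast
   upstroke matters: with a slow symmetric pulse the systolic flow gate
   would open after early reflections arrive.
2. Forward increments are `dA₊ = dQ₊/c`; the reflected wavelet is a
   Gaussian `dA₋ > 0` compression lobe at the drawn arrival (width 12 ms),
   scaled so its intensity integral is exactly the drawn BCW magnitude,
   followed 8 widths later by a 2.5×-broader expansion lobe of equal net
   area. The trailing lobe returns flow and area to their forward-only
   course — a lone compression bump would leave a standing diastolic flow
   offset — and is far and broad enough to perturb the BCW run-integral by
   only a few percent, inside the 10% recovery tolerance.
3. The construction speed `c` is made equal, by fixed-point iteration, to
   the chord (Bramwell–Hill) speed implied by the final waveform and drawn
   β. The analysis then separates with exactly the speed the waves were
   built with, which is what makes injected-wave recovery a sharp test; the
   tangent tube-law speed `√(β p_d/ρ)` is stored alongside. The chord
   exceeds the tangent by the factor `√((e^{βx}−1)/(βx))` at relative area
   excursion `x`, about 7–20% over the generated range, largest for the
   stiffest patients.
4. Central pressure follows the exponential law; the brachial systolic
   applies an amplification factor (1.08–1.20) to the true central peak;
   the mean is the model curve's time average. Resistance and TAC ground
   truths are the model-implied values at the true inputs.
5. Left-ventricular mass is linear in log BCW magnitude, BSA and sex, plus
   noise — so the adjusted regression has a known slope (default 18 g per
   log-unit) to recover.

Group defaults emulate a repaired-coarctation study: 50 patients / 25
controls; patients draw a stiffer tube law (β 3.2–5.6 vs 1.7–3.1, giving
wave speeds near 6–8 vs 4–6 m/s), a mildly dilated root (5.0–7.0 vs
4.4–6.2 cm²), a larger BCW (lognormal geometric means 2.0 vs 1.4 cm⁵ —
the 1.43 group ratio of the motivating clinical observations — with sdlog
0.35/0.32) arriving earlier (88 ± 8 ms vs 111 ± 10 ms after the R-wave,
truncated below at ejection onset + 40 ms, the earliest physical round
trip). The dispersions come from a variance budget: with these group sizes
the designed contrasts (c-SBP, BCW magnitude, BCW arrival) are detectable
at Welch p < 0.05 with comfortable power, which is the generator's
contract.

Measurement noise is band-limited — white noise convolved with a Gaussian
kernel (correlation ≈ 2 samples) — because registration-based segmentation
of beat-averaged images produces temporally smooth curves; per-sample white
noise would be amplified without bound by increment differencing and is not
a realistic model of that pipeline. Amplitudes are 0.002 cm² (area; the
residual compatible with the ~2 mmHg c-SBP repeatability of the
calibration, given that the diastolic anchor is a sample minimum and
therefore biased downward by noise) and 5 mL/s (flow, about 1% of peak).

What passing tests do and do not show: the generator shares the analysis's
model family (exponential tube law, single reflected wavelet, stationary
noise), so recovery tests validate the inference machinery, not the model's
adequacy for real aortas. Real data add segmentation bias, beat-to-beat
variation, multiple reflection sites and non-exponential pressure–area
behaviour, none of which the cohort emulates.

## The 1D scenario model

The simulator is a reduced single-aorta network, not a published multi-organ
arterial tree: five linearly tapered elastic segments (ascending aorta,
arch, proximal descending, isthmus, descending aorta), a time-varying
elastance ventricle with diode valves at the inlet, one lumped
upper-body windkessel at the distal arch junction, and a three-element
windkessel termination. Only qualitative claims are made with it, so its
defaults are package choices tuned to give control-like root pressures
(~125/80 mmHg at ~5.5 L/min); the packaged JSON
(`extdata/aorta_network_default.json`) is user-overridable.

Numerics: Richtmyer two-step Lax–Wendroff on the conservative form of the
1D equations with a linear-elastic tube law `A = A_ref(1 + D(p − p_ref))`
and Poiseuille friction; characteristic (Riemann-invariant) coupling with
Newton solves at the valve, junctions and terminals; Lapidus artificial
viscosity (gradient-activated, vanishing as dx²) to suppress sawtooth
modes; boundary half-cells updated conservatively with the same face fluxes
that the volume accounting uses, so inflow minus outflow matches tube
storage change to machine precision — except where the half-cell update
would exceed its stability bound (Courant number above 0.45, which happens
only inside a 10⁵-stiffened segment whose cells store essentially no
volume), where the characteristic state is kept. The time step satisfies a
per-segment CFL bound with a distension margin taken from the tube law
itself, and a state-based CFL audit runs during integration. Convergence is
declared when the root-pressure cycle differs from the previous cycle by
less than 0.5 mmHg (max-norm, default; at most 20 cycles), and the
simulation starts pressurised near the working point (95 mmHg) to shorten
the transient.

Scenario conventions: `narrow` multiplies the isthmus diameters by 0.75
with distensibility unchanged; `narrow_stiff` additionally divides its
distensibility by 1e5. The isthmus carries a finer default grid (48 nodes
for 2.5 cm) than the compliant segments because the reflection off a short,
nearly rigid segment is governed by its effective inertance, which the
junction half-cells represent only to first order in dx; at this resolution
halving every dx moves the root BCW magnitude by about 1%. The
matched-impedance uniform-tube control runs at a deliberately small pulse
(a few mmHg): a resistive load equal to ρc/A is reflectionless only in the
small-signal limit, and at physiological amplitudes the area-dependence of
the wave speed itself masquerades as ~10–20% reflection under fixed-speed
separation. The travel-time check compares the delay between the incident
(FCW) and reflected (BCW) intensity peaks with the round trip to the
stiffened segment — the reflected wave is a delayed copy of the incident
one, so peak-to-peak is the well-defined delay; ejection onset is not,
because the valve opens when ventricular pressure crosses aortic pressure,
well after activation begins.

## Cohort statistics

`summarize_groups()` reports arithmetic means with 95% t-intervals, or
geometric means (log-scale analysis) for the conventionally right-skewed
metrics (wave magnitudes, reflection magnitude); non-positive values under
a log transform are a hard error, never silently dropped. Both the pooled
and Welch two-sample tests are computed; the reported p-value uses Welch
when the group variance ratio exceeds 2. Binary metrics (central
hypertension c-SBP > 125 mmHg, brachial hypertension p-SBP > 140 mmHg —
strict inequalities) get proportion tests. The LVM regression is ordinary
least squares of LVM (g) on natural-log BCW magnitude adjusted for BSA,
age, sex and case/control status, with rank deficiency reported rather
than repaired; `lvm_univariable()` fits each candidate metric with the same
adjusters. No multiple-testing correction is applied (α = 0.05), matching
the descriptive intent.

## Problem sizes and determinism

The shipped tests run the separation identities on 1000 random sequences,
calibration and wave recovery on 40-subject zero-noise batches, windkessel
recovery on 20 random (R, C, flow) triples against the RK4 oracle, the full
default cohort (75 subjects) once, and the three 1D scenarios with one
grid-halving of the stiff case. Everything stochastic draws from R's
generator under explicit seeds; the 1D solver is deterministic. Known
limitations: the cohort shares its model family with the analysis (above);
the 1D model makes no patient-specific or quantitative claims; brachial
amplification is a drawn factor, not a propagation model, so the generator
does not reproduce the clinical observation that brachial pressures can be
group-indistinguishable while central pressures differ.
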