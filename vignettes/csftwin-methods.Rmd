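---
title: "Methods: a lumped-parameter twin of craniospinal CSF dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lumped-parameter twin of craniospinal CSF dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csftwin)
```

## The system being modelled

Cerebrospinal fluid (CSF) surrounds the brain and spinal cord. Because the
cranium is rigid (the Monro–Kellie doctrine), the pulsatile difference
between arterial inflow to and venous outflow from the head — the
arteriovenous (AV) flow, roughly 0.8 ml per heartbeat — must be absorbed by
displacing CSF from the cranial to the more distensible spinal compartment
during systole, and back in diastole. The resulting cervical CSF flow
oscillation (on the order of ±100 ml/min at the C2–C3 level) and the
intracranial pressure (ICP) pulse are the two clinically accessible
signatures of craniospinal coupling; both are disturbed in conditions such
as normal pressure hydrocephalus.

`csftwin` is a lumped-parameter hydraulic model of a laboratory bench that
reproduces this coupling with water, trapped-air compliance chambers,
adjustable valves and a tube-segment spinal canal, driven by a cam-disc
piston pump. The package simulates the network, synthesizes the pump's
driving waveform and cam contour, and computes the validation metrics used
to compare such a bench against cardiac-gated PC-MRI flow recordings and
published ICP ranges.

## Network topology

The model is a four-node hydraulic network with two storage elements:

```
pump ──► N1 (cranial chamber) ──[valve 1 + aqueduct path]──► N2 ──► N3
              │                                                    ▲
              └──────────────[valve 2: cranial SAS]────────────────┘
N3 (cistern) ──[spinal canal, series Poiseuille segments]──► N4 (spinal chamber)
```

* **N1** carries the cranial compliance chamber; the pump injects the AV
  flow here.
* The **valve-1 path** lumps the adjustable valve and the
  parenchyma/aqueduct route as one series resistance. The box around the
  parenchyma is rigid and water incompressible, so this path carries no
  storage; the ICP sensor node **N2** sits inside it, a configurable
  fraction (`valve1_fraction`, default 0.5) of the path resistance
  downstream of N1.
* **Valve 2** is the flow resistance of the cranial subarachnoid space.
* **N3** (the cistern) carries no storage, so its pressure follows
  algebraically from the chamber pressures.
* The **spinal canal** is a series of circular ducts with physiological
  hydraulic diameters (defaults 15/10/5 mm over 60 cm) and laminar
  Hagen–Poiseuille resistance $R = 128\mu L/(\pi d^4)$. Peak Reynolds
  numbers stay laminar (about 500–700), so no turbulence corrections are
  applied.
* **N4** carries the spinal compliance chamber.

A consequence of this topology worth knowing: the valve-1 path and valve 2
connect the same two nodes, so the flow dynamics depend on the two valve
resistances only through their **parallel combination**. Calibration (below)
is well-posed for that combination and degenerate along the split; the
fitted object therefore exposes `r_parallel` as the quantity to compare
across runs.

## Air-chamber compliance

Compliance is volume stored per unit pressure rise, $C = dV/dp$. Each
chamber traps an air pocket of initial volume $V_0$ at absolute pressure
$p_0$ above the water column. Pulsation is fast relative to heat exchange,
so the gas follows the isentropic law $p_0 V_0^{\lambda} = p V^{\lambda}$
with $\lambda = 1.4$ for air (configurable down to 1.0, the isothermal
limit appropriate for very slow cycles). Differentiating gives the
pressure-dependent compliance

$$C(p) = \frac{1}{\lambda}\, p_0^{1/\lambda}\, V_0\, p^{-\frac{1+\lambda}{\lambda}},$$

which collapses to $C(p_0) = V_0/(\lambda p_0)$ at the reference state.
Two points deserve emphasis:

* **Absolute pressure.** The gas law is physically meaningful only in
  absolute units. All chamber arithmetic therefore runs on
  `760 mmHg + gauge`; reported pressures are gauge. Using gauge pressures
  (~13 mmHg) in the gas law would imply absurd chamber volumes.
* **Sizing.** A chamber is specified either by its air volume or by a
  compliance target; `size_air_volume()` inverts the collapse formula,
  giving $V_0 = C\,\lambda\,p_{\mathrm{op}}$ — about 335 ml of air for
  0.31 ml/mmHg and 909 ml for 0.84 ml/mmHg at a 12.68 mmHg baseline.

The default budget splits 1.15 ml/mmHg total compliance into 0.31 cranial
and 0.84 spinal. Computed as percentages these are 27% and 73%;
`total_compliance()` always reports shares computed from the values (some
published tabulations quote a spinal share inconsistent with their own
numbers, and this package does not try to reproduce such rounding).

## The driving waveform

Published AV curves are not available as numbers, so the package generates
parametric stand-ins (with CSV import for digitized curves):

* **Arterial inflow**: a mean cerebral inflow (700 ml/min) plus a wrapped
  Gaussian systolic lobe (peak time 0.15 s, width σ = 0.08 s). The lobe
  amplitude default (601.4 ml/min) is fixed so the final AV waveform
  carries a stroke volume of 0.8 ml.
* **Venous outflow**: the arterial waveform circularly shifted by an
  arteriovenous transit delay (0.09 s) and flattened by circular Gaussian
  smoothing (σ = 0.13 s) — the low-pass effect of the venous reservoir.
  Both operations conserve cycle volume exactly; `match_venous_volume()`
  then applies a single scale factor (exactly 1 for this pipeline) so the
  AV difference carries zero net volume.
* **AV flow** = arterial − venous. Zero net cycle volume is not cosmetic:
  the model is sealed, so any net volume would make pressures drift
  monotonically, and the cam contour would not close.

The venous delay and smoothing defaults were chosen once, by design: they
give the AV waveform the caudal:cranial peak asymmetry (about 2:1) seen in
published recordings, which in turn lets the calibrated network reproduce
measured bidirectional cervical flow extrema. They are ordinary config
parameters for sensitivity studies (ageing can be emulated by increasing
the AV delay, reduced pulsatility by lowering the lobe amplitude).

## Integration scheme

`simulate_network()` integrates the two chamber air volumes with a
classical fixed-step 4th-order Runge–Kutta scheme at `dt = period/2048` by
default. A fixed step keeps every cycle boundary exactly on a grid point
(cycle-mean statistics need no interpolation) and makes runs
bit-reproducible; there is no step-size control to introduce
platform-dependent branching. The cistern pressure is eliminated
algebraically at each stage, so the ODE state stays two-dimensional and
volume conservation holds to round-off by construction. Two warm-up cycles
(matching the bench's two priming rotations) are integrated and discarded;
the start-up transient decays with a time constant of roughly 0.14 s, so
the periodic steady state is reached to ~1e-6 well within the warm-up.

**Baseline referencing.** Over a cycle the piston's cumulative displaced
volume has a non-zero time average $\bar V$ (~0.3 ml for the default
waveform), which raises the sealed system's mean pressure by
$\bar V / C_{\mathrm{total}}$ (~0.26 mmHg). A physical bench is zeroed
while running; the simulation reproduces this by starting both chambers at
the common pressure `baseline − V̄/C_total`, after which the cycle-mean ICP
equals the configured baseline to within ~1e-4 mmHg (the residual is the
second-order effect of chamber nonlinearity).

## Valve calibration

The bench's valve settings are hand-tuned and unpublished, so the twin
recovers them from flow data: `calibrate_resistances()` minimizes the
summed squared relative mismatch between simulated and target spinal-flow
extrema over the two valve resistances, using an 8×8 log-spaced grid scan
(bounds 1e-4 to 1 mmHg per ml/min) followed by Nelder–Mead refinement in
log space. The procedure is deterministic — fixed grid, fixed start, no
randomness. Inside the objective the simulation runs at a coarser grid
(`period/512`, 2 recorded cycles) for speed; the reported extrema always
come from a full-resolution run. A fit that cannot reach the configured
tolerance (5% per extremum) returns a report with `converged = FALSE` and
the residuals rather than throwing.

Against the reference extrema (133.60 / −68.01 ml/min) with the default
chambers and pump, the fit converges with residuals under 2%, and the
calibrated twin's spinal stroke volume (~0.37 ml/cycle), ICP pulse
amplitude (~1.2 mmHg) and mean ICP (12.68 mmHg) sit inside the published
physiological ranges. One timing signature separates a static-compliance
model from in vivo behaviour: with purely static (air-pocket) compliance
the cranially directed flow maximum arrives early, at ~32% of the cycle
after the caudal maximum in this configuration, whereas PC-MRI cohorts
place it around 63%. The early arrival is the expected signature —
viscoelastic (dynamic) compliance, deliberately out of scope here, is the
mechanism thought to delay it.

## Metrics

* **Stroke volume**: integral of the positive (caudal) lobe of the
  cycle-mean flow, in ml per cardiac cycle. With zero net volume this
  equals the negative-lobe magnitude, so the caudal-lobe definition is
  canonical. On the uniform closed-open cycle grid the Riemann sum *is*
  the trapezoidal rule of the periodic extension.
* **Bidirectional extrema**: max/min of the cycle(-mean) flow,
  caudal-positive, the cranial maximum reported negative.
* **Phase of the cranial maximum**: the cycle is re-anchored with the
  caudal maximum at 0% and the global minimum's position reported as a
  percentage. Ties break to the earliest sample; flat waveforms return
  `NA` with a warning. The metric is invariant under circular shifts by
  construction.
* **ICP pulse statistics**: cycles are split minimum-to-minimum (or at
  exact simulation cycle marks), resampled onto a common 0–100% grid, and
  summarized by the all-sample mean, global extrema, and the
  cycle-to-cycle spread of per-cycle extrema. On the mean cycle, peaks are
  detected after moving-average smoothing (window 5% of the cycle) with a
  prominence filter of 5% of the pulse range — sub-ripple bumps are not
  pulse peaks. MWA is the first peak's height above the cycle-start
  minimum; P2:P1 is the ratio of the first two peaks' heights above that
  minimum, `NA` when fewer than two peaks survive (as for this twin's
  single-peaked ICP).
* **Cohort comparison**: per-metric difference from the cohort mean,
  min–max envelope membership, and the timing offset between
  cranial-maximum phases.

## The synthetic cohort generator

PC-MRI subject curves are not published as numbers, so
`template_cervical_flow()` builds a parametric healthy-subject template —
an early caudal Gaussian lobe and a broader cranial return placed 63% of
the cycle later, with amplitudes and the caudal width fixed-point–iterated
so the sampled extrema equal 122.82 / −77.86 ml/min and the stroke volume
0.385 ml. `synth_cohort()` then draws subjects with independent relative
amplitude jitter per lobe (SD 0.15, emulating the reported 20–30% spread
of cohort extrema) and a circular timing jitter (SD 3% of the cycle).
`add_sensor_noise()` models an ultrasonic flow sensor as additive Gaussian
noise with σ = accuracy/2, reading a manufacturer's "accuracy" figure as a
±2σ half-width; the reference sensor's 6 ml/min figure thus becomes
σ = 3 ml/min.

What the generator deliberately does **not** emulate: beat-to-beat heart
rate variability (curves are gated to one cycle), respiratory modulation,
production/absorption of CSF, PC-MRI partial-volume or phase-unwrap
artifacts, and any correlation between a subject's amplitude and timing.
Tests that pass on this cohort therefore demonstrate correct bookkeeping
and unbiased averaging of the package's statistics, not robustness to real
acquisition artifacts.

## Cam-disc synthesis

One cam revolution corresponds to one cardiac cycle. The piston
displacement is the cumulative displaced volume (trapezoidal rule) divided
by the piston area (default: 9 mm bore, the 2 ml-syringe class), normalized
to a zero minimum; the contour is `r(θ) = base_radius + x(θ)` for an
idealized radial knife-edge follower (roller-radius compensation is an
explicit non-goal; the argument exists and must be zero). Trapezoidal
integration is chosen so that central differencing of the exported contour
reconstructs the input flow to ~0.1% RMS at 256 samples — the round-trip
check shipped in the test suite. Exports are full-precision CSV with
metadata headers, so export/import round trips are bitwise.

## Numerical choices and degenerate inputs

* Waveforms require ≥ 32 uniform samples (the temporal resolution of gated
  PC-MRI); the default grid is 256 samples, a power of two for clean
  resampling against the `period/2048` integrator grid.
* Zero-net-volume checks use 1e-9 ml on waveform construction paths and a
  1e-6 ml refusal threshold in the simulator and cam generator.
* The waveform CSV reader enforces grid uniformity to 1e-6 s and names the
  first offending row; single-row files are rejected (no grid).
* Configuration validation rejects unknown keys by full path name; a
  chamber accepts `v0_air_ml` or `c_target_ml_per_mmHg`, never both.
* Percentage shares round half-up (not banker's rounding) for parity with
  tabulated distributions.
* Flat traces: extrema are equal, phase metrics return `NA` with a
  warning, pulse peaks are flagged `NA` rather than invented.

## Problem sizes

The shipped tests and the acceptance script run the full-resolution
configuration everywhere it matters: nine recorded cycles at 2048 steps
per cycle for reported results, with the coarser `period/512` grid used
only inside calibration objectives (whose result is always re-evaluated at
full resolution). The Monte-Carlo unbiasedness check of the cohort
generator uses 300 subjects. A complete calibration plus validation run
takes a few seconds on one core.

## Known limitations

* Static compliance only: the air pockets respond instantaneously, so the
  twin reproduces the early cranial-flow maximum of a static bench, not
  the in vivo timing. Dynamic (viscoelastic) compliance is future work.
* Supine geometry only — no hydrostatic terms, so posture studies are out
  of scope.
* No CSF production/absorption, respiration, or shunt/implant elements.
* The valve split (valve-1 path vs valve 2) is structurally unidentifiable
  from spinal flow alone; only their parallel combination is meaningful,
  and the ICP tap position along the valve-1 path is a modelling constant,
  not a fitted quantity.
* Laminar canal resistance throughout; entrance and minor losses are
  neglected, which is justified at physiological Reynolds numbers but not
  for stenosis studies at much higher flows.
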