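---
title: "Volumetric capnography of spontaneous breathing: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Volumetric capnography of spontaneous breathing: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volcap)
```

## The measurement and its model

A mainstream volumetric capnograph samples two synchronized channels at
100 Hz: airway flow (L/min, signed) from a variable-orifice
differential-pressure sensor, and CO₂ partial pressure (mmHg) from an
infrared sensor sitting directly in the gas stream. `volcap` represents a
recording as a `sample_series`: integer millisecond timestamps on an exact
10 ms grid, so the grid invariant never depends on floating-point
comparisons. The 10 ms interval is a hardware property (mainstream CO₂
sensors top out at 100 Hz); the flow channel natively samples faster
(0.5 ms) and is averaged per 10 ms window, which `downsample_flow()`
reproduces (trailing partial windows are dropped so every output is a mean
of the same number of native samples).

Positive flow is expiration throughout. The hardware convention depends on
how the flow sensor is mounted, so readers flip polarity with
`invert_flow` rather than the package assuming one.

PCO₂ must lie in [0, 150] mmHg; the sensor class is characterized to
100 mmHg and values above 150 are physically implausible, so they are
rejected as data corruption rather than clamped.

## Breath segmentation

Cycles are delimited by flow reversals. Raw zero crossings are hopeless at
clinical noise levels (~0.2–0.5 L/min around zero), so `segment_breaths()`
uses a Schmitt trigger with debounce:

* **deadband** (default 0.5 L/min): a phase change is only *considered*
  when flow strictly changes sign, and only *confirmed* once flow exceeds
  the deadband in the new direction;
* **min_phase** (default 150 ms): the new phase must persist this long —
  a beyond-deadband return to the old sign cancels the candidate;
* **apnea limit** (default 2 s): near-zero flow longer than this closes the
  cycle instead of stretching expiration indefinitely; the remainder of the
  pause is reported as an incomplete "gap" row.

A confirmed reversal is then *refined* to the extremum of the running
signed volume (cumulative flow) near the first raw sign change. This is the
physically meaningful boundary — the instant lung volume turns around — and
integrating averages the noise out. On noiseless data the extremum falls
exactly on the last sample before the zero crossing, so the refinement is
invisible in clean examples; deterministic clamps guarantee that
sub-deadband blips and exact-zero samples always stay with the phase being
exited, and that the boundary never passes the first beyond-deadband sample
of the new phase. We also evaluated one- and two-sided least-squares
zero-crossing estimators: the two-sided fit is biased by a full sample
whenever Ti ≠ Te (the flow slope is discontinuous at the reversal) and the
one-sided extrapolation is noisier on slow, shallow breaths; the volume
extremum dominated both.

Cycles are inspiration-first. A record beginning mid-expiration yields a
leading partial row (`complete = FALSE`), a trailing inspiration without
its expiration likewise; complete cycles tile the record exactly
(`i_start = previous i_end + 1`), which the tests assert as a conservation
law.

### Phase times and a deliberate one-sample bias

Ti and Te follow the field's tabular convention: the time difference
between the last and the first sample of each phase,
`Ti = t[i_rev − 1] − t[i_start]`. A phase containing *n* samples spans
`(n − 1)·dt`, so this estimator underestimates the continuous phase
duration by one sample period on average (error deterministically in
`(−2dt, 0]`). We keep the convention because it is what bench software
reports, and document the bias instead of silently "fixing" it; the
acceptance tests check recovery against simulator ground truth with the
bias made explicit (`|Ti_rec + dt − Ti_true| < dt`). Anyone needing an
unbiased duration can add `dt` — the boundaries themselves are recovered to
±1 sample on clean data.

## Per-cycle parameters

All integrals are rectangular (left) sums at the record's own `dt`,
mirroring firmware-style fixed-step integration; flow converts as
1 L/min = 1/60 mL/ms.

* **Vi, Ve** — `Σ |flow| · dt` over each phase (mL).
* **VCO₂/br** — `Σ flow·PCO₂ / Patm · dt` over the whole cycle, signed
  flow. Whether the inspiratory limb should be skipped or signed is
  ambiguous in the field; with inspired PCO₂ ≈ 0 (no rebreathing,
  mainstream sensor) the choices agree to well under 0.5 %, and we use the
  signed full-cycle sum. `Patm` defaults to 760 mmHg and is configurable;
  no BTPS/ATPS gas-condition correction is applied (volumes are at
  measurement conditions).
* **ETCO₂** — PCO₂ at the sample where cumulative expired volume is
  maximal, ties to the earliest such sample: if flow dies before the
  nominal end of expiration while the PCO₂ reading drifts, the value at the
  start of the volume plateau is reported.
* **PEF** — max |flow| over expiration, reported in L/min (the natural unit
  for resting peak flows of 20–35).

## The volumetric capnogram and its slopes

`build_capnogram()` plots PCO₂ against cumulative expired volume.
Negative-flow samples inside an expiration contribute zero volume increment
(and raise a flag), so the volume axis is non-decreasing by construction.

**Phase III** is fitted by OLS of PCO₂ on volume over samples with
`0.40·VT ≤ v ≤ 0.80·VT` — inclusive bounds, no interpolation onto the exact
fractional volumes (bias-free at 10 ms resolution and simpler; at ~100
points per expiration the sample straddling a bound is immaterial). The
slope is reported in mmHg/L together with a dimensionless VT-normalized
variant, `slope · VT / mean window PCO₂`, following the normalization used
in the clinical literature. A zero-variance plateau yields slope 0 with
r² defined as 0 (warning, never NaN). `slope3_variability()` summarizes the
cycle-to-cycle scatter as a CV in % with the sample-SD (n−1) convention —
on simulated spontaneous breathing with 30 % slope jitter it reports CVs in
the 20–40 % range, the order of magnitude seen in resting volunteers.

**Phase II** has no canonical window. `fit_slope2()` uses an explicit,
configurable, *experimental* convention: center on the steepest 3-sample
central-difference gradient of PCO₂ vs volume and expand while the local
gradient stays ≥ 50 % of the peak. Note a mathematical consequence: for a
logistic upstroke the OLS slope over the half-peak-gradient window is
≈ 0.87 × the analytic peak gradient (a secant always underestimates a
maximum derivative); the tests therefore check against the analytic
OLS-over-window value, not the peak gradient.

Because phase II is steep, its estimate benefits most from fast sampling;
phase III is insensitive — the same analytic breath sampled at 5 ms and
10 ms changes the fitted slope III by < 1 % (asserted in the acceptance
suite).

## Static calibration

`fit_linear_calibration()` regresses measured on reference (gain is
orientation-dependent; this orientation makes the gain directly applicable
to raw readings) and reports R², a 95 % CI on R² via the Fisher
z-transform of r with the bounds squared — a stated convention, since bench
reports rarely say how their CI was computed — and per-point 95 %
prediction-interval half-widths from the standard OLS prediction variance.
The canonical bench designs are built in: flow at 0–45 L/min in 5 L/min
steps, 5 repetitions in each direction (100 measurements); CO₂ at 11 set
points to 100 mmHg, 3 repetitions at each of 5 carrier flows (165
measurements). `emulate_static_bench()` generates seeded synthetic bench
data for recovery testing; `apply_calibration()` implements
`corrected = cf · (gain·raw + offset)`, the firmware-style multiplicative
slope correction.

## Device comparison

`compare_tables()` reproduces the familiar comparison layout: per-parameter
mean ± SD in each group and an unpaired two-sided Mann-Whitney test. The
exact p-value is computed by full enumeration of the U distribution
(dynamic programming over rank arrangements) when the data are tie-free and
`n_x·n_y ≤ 400`; otherwise the normal approximation with tie and continuity
corrections applies. The threshold and the tie convention are this
package's choices, both configurable. Devices measured in series produce
*paired* cycles, yet the unpaired test is the field's habit; a paired
Wilcoxon would be more powerful and the data model supports adding one, but
the default deliberately matches common practice. No multiple-testing
correction is applied by default (`holm = TRUE` is available).

## The breathing simulator: what it emulates, and what it does not

`simulate_breathing()` is the test substrate for everything above. Per
breath it draws VT, Ti, Te, ETCO₂ and slope III from clamped normal
distributions, then constructs:

* **flow**: a half-sine per phase, amplitude `VT·π/(2T)`, so each phase's
  integral equals the drawn VT exactly (closed form);
* **expiratory PCO₂**: a logistic phase II upstroke (steepness
  `phase2_sharpness` = 40 in inverse-VT-fraction units, midpoint at 15 % of
  VT) joining a phase III *linear in expired volume* — matching how slope
  III is defined — whose endpoint is exactly the drawn ETCO₂ (the sigmoid
  is normalized to 1 at v = VT);
* **inspiratory PCO₂**: exponential washout to 0 mmHg (τ = 120 ms), i.e.
  no rebreathing;
* white Gaussian noise per channel, added last; PCO₂ clamped at 0.

Defaults describe a healthy resting adult on a mouthpiece — VT 500 mL
(CV 12 %), Ti 1.8 s, Te 2.4 s (CV 8 %), ETCO₂ 34.9 ± 0.8 mmHg, slope III
10 mmHg/L (CV 30 %), flow noise 0.2 L/min, PCO₂ noise 0.3 mmHg — the scale
reported for healthy volunteers on such devices. Ground truth (including
continuous, non-grid-snapped phase switch times) is returned alongside the
record, and a fixed seed reproduces the output bit-for-bit without
disturbing the caller's RNG stream.

The simulator does **not** emulate: cardiogenic oscillations, autocorrelated
sensor drift, coughs/swallows/leaks, disease-specific waveform shapes, or
rebreathing. A green test therefore establishes correctness of the signal
processing under idealized single-breath morphology with white noise — not
robustness to every artifact a clinic produces.

## Numerical choices and edge cases

* Rectangular (left) integration at dt = 10 ms everywhere, to mirror
  fixed-step firmware; the fine-grid (0.1 ms) comparisons in the tests show
  per-breath volumes and CO₂ volumes agree with continuous integrals to
  ≪ 1 % for physiological waveforms (half-sine flow vanishes at phase
  boundaries, which suppresses the leading-order quadrature error).
* Exact-zero flow at a boundary belongs to the phase being exited;
  boundaries are deterministic, segmentation is idempotent.
* Degenerate fits raise classed conditions (`volcap_numeric_error`) rather
  than returning NaN: < 3 samples in a slope window, a flat capnogram for
  phase II, rank-deficient calibration designs.
* The CLI maps condition classes to exit codes (2 config, 3 data format,
  4 numeric), and all artifacts are deterministic in config + seed (no
  timestamps), so reruns are byte-identical.

## Known limitations

* Boundary recovery degrades for slow, shallow breathing (peak flows near
  the deadband, e.g. Ti > 3 s with VT < 500 mL): the flow slope at the
  reversal approaches the noise floor and no estimator can localize the
  crossing well. At the default resting pattern, ≥ 95 % of boundaries fall
  within ±2 samples at flow noise σ = 0.5 L/min; expect worse outside it.
* ETCO₂ is read off a single sample, so its error is the sensor noise at
  that sample (σ ≈ 0.3 mmHg); no smoothing is applied because smoothing
  would bias the plateau endpoint on steep phase III slopes.
* Sidestream capnography (sampling-line transport delay) is out of scope;
  the alignment assumptions hold for mainstream sensors only.
* The phase II slope convention is experimental and should not be compared
  across software without checking the window definition.
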