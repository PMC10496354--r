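---
title: "Online gating control for MRI-guided radiotherapy: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online gating control for MRI-guided radiotherapy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respgate)
```

## The problem

Amplitude-based beam gating keeps the radiation beam on only while the target
sits inside its gating window. On an MR-Linac the target position comes from
2D cine-MR at 5 Hz (one sample every ΔT = 0.2 s), and the end-to-end system
latency — image acquisition, contour-based tracking, beam on/off triggering —
is about 0.5 s. A controller that simply reacts when the observed trace
crosses the gating threshold is therefore late by the full latency at every
beam transition. `respgate` implements a patient-specific online controller
that forecasts the trace slightly beyond the latency, estimates *when* the
threshold will be crossed, and issues each beam command that far in advance.

This vignette documents the model, the tunable parameters, the synthetic-data
generator the tests rely on, and the design decisions taken where the problem
statement left the design genuinely open.

## Prediction model

For a channel `y` (SI by default, mm) and window length `m = 15` samples
(about 3 s), each anchor time `T_i` yields the input window
`x_i = (y(T_i - (m-1)ΔT), ..., y(T_i))` and the two-horizon forecast

    yhat_(i,j-1) = x_i' b_(j-1),   yhat_(i,j) = x_i' b_j,

a pure inner product — no intercept, since the forecast should scale with the
window and the window already carries the baseline. An optional penalty gives
three fitting modes:

* **OLS** minimizes the residual sum of squares. Rank-deficient designs
  (possible on noiseless, low-complexity traces) take the minimum-norm
  solution via the SVD, so the fit is deterministic.
* **Ridge** adds `λ ||b||²`. λ is selected by leave-one-out cross-validation
  computed in closed form from the ridge leverages (`e_i / (1 - h_ii)`), so
  the N explicit refits are never performed. Default grid: 20 log-spaced
  values in `[1e-4, 1e2]`.
* **L2–L1 (lasso)** adds `λ ||b||₁`, minimized by ADMM (ridge-like primal
  update, soft-thresholding, dual ascent). We write the objective as
  `0.5 ||y - Xb||² + λ ||b||₁`, the convention under which the smallest
  all-zero penalty is exactly `λ_max = max |X'y|`; any other scaling only
  relabels λ. λ is selected by generalized cross-validation,
  `GCV(λ) = N·RSS / (N - df)²`, with `df` the number of nonzero coefficients
  — the conventional unbiased df estimate for the lasso; saturated fits
  (`df = N`) are skipped. The ADMM penalty parameter defaults to
  `max(1, λ/10)`, which keeps the splitting step on the scale of the
  regularizer; the optimum does not depend on it, only the iteration count.
* **Kalman baseline**: a constant-velocity (white-noise-acceleration) filter
  with configurable noise variances (`q = 10 mm²/s³`, `r = 0.1 mm²` by
  default), extrapolated to the two horizons. It is included as the classical
  comparator; on fast, strongly curved breathing its extrapolations overshoot
  at the turning points and it detects fewer crossings than the regressions.

Two horizons are supported: `j = 2` (0.4 s, *under-prediction*, shorter than
the latency) and `j = 3` (0.6 s, *over-prediction*). Both coefficient vectors
are fitted independently, one per label column, as the per-horizon loss
functions are separate.

### Static and adaptive training

The static mode mirrors an offline study: windows are split chronologically —
first 70% training pool, last 30% test, with the most recent 20% of the pool
held out as a validation block. Chronological (never shuffled) splitting is
the only defensible choice when labels are future samples; a random split
would leak the test period into training. Sizes floor toward validation and
test, remainder to train (N = 100 gives 56/14/30). Ridge and lasso select
their penalty on the training block via LOOCV/GCV, which need no held-out
data; the validation block exists for schemes that do need one.

The adaptive mode is the clinical proposal: fit after a 30 s burn-in
(150 samples) and refit on an ever-growing buffer while predicting. The
buffer respects label availability — the pair `(x_i, y_(i,k))` enters only at
`T_i + kΔT`, when its label has actually been observed, so the model never
trains on the future it is asked to predict. Each refit is a full
least-squares solve on the buffer; at `m = 15` and a few thousand samples
this costs well under a millisecond, so a recursive fast path is unnecessary.
`refit_every = Inf` disables adaptation after the burn-in fit, which is how
the static-at-burn-in comparator in the burn-in sweep is produced; the test
suite verifies that the streaming refits equal batch refits-from-scratch at
every step.

## Crossing-time estimation and trigger logic

The predicted crossing time interpolates the forecast pair linearly across
the threshold `Th`:

    That_cross = (Th - yhat_(i,j)) / (yhat_(i,j) - yhat_(i,j-1)) · ΔT
                 + T_i + j·ΔT,

algebraically the standard two-point interpolation written from the far
horizon. `Th` is the mean of the channel over the burn-in (a low threshold
gates on the quiet exhale phase). Reference (gold-standard) crossings apply
the same interpolation to consecutive *observed* samples; a sample exactly on
the threshold is assigned that sample's time, with the direction read from
the following movement. The *ideal* gating signal leads every reference
crossing by exactly the latency.

At each anchor the controller fires on one of two conditions:

* **A (bracketed)**: `Th` lies between the two forecasts — the crossing is
  inside the forecast interval and the interpolation is exact up to
  prediction error.
* **B (pre-trigger)**: the extrapolated crossing lies at most
  `dt_max = 0.1 s` beyond the far horizon. This margin is not decorative:
  with `j = 3` the horizon exceeds the latency by exactly `ΔT - dt_max`, so
  crossings that would otherwise be detected too late to schedule are caught
  one sample early.

The toggle direction follows the predicted slope (descending = crossing-on =
beam on, under the default `beam_on_below`); a flat pair never triggers. A
second detection of the same crossing — same direction, crossing estimates
within the refractory window (default = latency) — emits nothing new: if the
pending toggle came from a pre-trigger and the new detection brackets, the
bracketed estimate *refines* the extrapolated one; otherwise the duplicate is
dropped. Transition lists are normalized to strictly increasing times with
alternating states.

### Scheduling, causality and the two prediction windows

Commands are scheduled at `That_cross - latency`, floored at `dt_max` before
the decision that produced the final estimate. The floor encodes what the
hardware can honor: the 0.5 s latency is end-to-end *from image acquisition*,
so by the time the frame stamped `T_i` has been processed, part of that
budget is already spent; a command formed then can still realise a transition
up to the processing margin (taken as `dt_max`) before `T_i` on the
image-timestamp axis. Refinements move the floor with the refining frame — a
correction may not reach further back than the margin of the decision that
issued it.

Two consequences, both verified to machine precision in the tests:

* For `j = 3`, bracketed estimates lie within `[T_i + 0.4, T_i + 0.6]`, so
  commands never hit the floor: per event, the gating error *equals* the
  crossing error, and an oracle predictor reproduces the ideal signal
  exactly.
* For `j = 2`, the horizon is 0.1 s short of the latency and the floor binds
  on most events: gating errors strictly exceed crossing errors (roughly
  100 ms on the synthetic cohorts) even though the crossings themselves are
  predicted slightly *better* at the shorter horizon. Over-prediction is the
  right choice whenever the latency is not a multiple of the sampling period.

The beam state before the first transition is inferred from the first
detected crossing — equivalent to initializing from which side of the
threshold the trace starts on; a hard "off" start is available via
`initial_state` for conservative protocols.

## Metrics

Amplitude: MAE, RMSE, R² (observed-mean baseline) at the far horizon.
Temporal: predicted events are paired one-to-one with same-direction
reference events by increasing time difference within a pairing window
(default half the mean breathing period); crossing/gating errors are the
absolute paired differences in ms. Unpaired (missed or spurious) events are
excluded from the error mean but counted, and they still depress gating
accuracy, which is computed independently as the exact overlap of the two
signals: `100·(1 - T_disagree / T_total)`, with the disagreement duration
obtained by an exact sweep over merged transition times — no binning error.
Paired model comparisons use the two-sided Wilcoxon signed-rank test.

## The synthetic-trace generator

Patient cine-MR traces cannot be redistributed, so the package ships a
simulator whose defaults are the study conditions for all tests. Each cycle
draws its own period `~ N(mean, sd)` (truncated above half the mean) and its
own SI excursion `~ N(mean, 10% of mean)` (truncated positive); within a
cycle the SI position follows `b · sin^(2n)(π u)` with `2n = 4`, an
exhale-rest profile: the trace idles near the exhale baseline and spends
little time at peak inhale, the asymmetry gating exploits. Cycle boundaries
sit on the plateau so amplitude changes never introduce jumps. AP and LR are
scaled, slightly phase-lagged copies of the clean SI waveform; a linear
baseline drift (0.5 mm/min) and i.i.d. Gaussian noise (0.3 mm, sub-pixel at
3 mm image resolution) are added per channel. The `liver` preset uses a
4.6 s mean period and 21.3 mm mean SI excursion, the `lung` preset 3.4 s and
16.2 mm; cohort simulation draws per-patient means from the corresponding
published ranges (liver period 2.9–7.4 s, SI 5.6–40.1 mm; lung 2.4–5.4 s,
3.1–25.2 mm) with range-truncated normals. The 3D total motion channel is the
per-sample Euclidean displacement from the per-axis series mean — a fixed
reference, which is what published per-axis mean amplitudes imply.

What the generator does *not* emulate: coughs, breath-holds, sudden pattern
changes, baseline shifts beyond linear drift, tracking dropouts, or the
amplitude-dependent noise of a real contour tracker. Passing tests therefore
demonstrate correctness of the machinery and its analytic properties, not
clinical performance. Two quantitative regime notes: the `sin⁴` profile is
steeper at mid-amplitude (where the threshold sits) than typical patient
breathing, so absolute temporal errors on synthetic cohorts run higher than
clinical reports (adaptive `j = 3` gating errors of 50–120 ms and accuracies
of roughly 88–96% here, against ~45 ms and ~98% reported on patients); and
occasionally a steep crossing falls in the gap between the forecast pairs of
consecutive anchors, with the pre-trigger margin missing it by a few tens of
milliseconds — a genuine vulnerability of the two-condition trigger under
biased predictions, visible as occasional missed transitions.

## Numerical choices and degenerate inputs

* Fixed seeds make every simulation bit-reproducible; the generator restores
  the caller's RNG state.
* Crossing interpolation uses one shared kernel for predicted and reference
  crossings, so the oracle identity holds to floating-point round-off
  (~1e-11 ms) rather than to an analytic tolerance.
* `λ = 0` is allowed in the ridge grid (it reduces to OLS exactly); negative
  penalties are rejected.
* ADMM stops when primal and dual residual norms drop below `tol = 1e-8`;
  hitting `max_iter` flags the result (`attr(, "converged")`) and warns
  rather than erroring, since a late-stage penalty sweep should not abort.
* Ties: a forecast pair exactly equal to the threshold returns the earlier
  horizon time; flat pairs never trigger; a sample exactly on the threshold
  is a crossing at that sample.
* Event matching is greedy by increasing time difference, one-to-one and
  direction-constrained; with jitter far below the breathing period this is
  the unique optimal assignment.

## Problem sizes

The test suite and the acceptance script run on desk-scale inputs chosen to
exercise every property at full precision: 120–300 s traces (601–1501
samples), cohorts of 2–4 traces, 10⁴-triple algebraic sweeps, and solver
oracles on 30×5 to 200×15 designs. The full suite completes in about half a
minute on one CPU.

## Known limitations

* The controller consumes a single channel; gating on the 3D total-motion
  channel is configurable but thresholds on it are less interpretable than on
  SI.
* The refractory deduplication (default = latency) merges genuinely distinct
  crossings closer than 0.5 s, which only matters for breathing far faster
  than the cohorts modeled here.
* The Kalman baseline is deliberately plain (constant velocity); no attempt
  is made to tune it per patient.
* Duty-cycle/treatment-time optimization, contour tracking, image simulation
  and dosimetric evaluation are out of scope: the package starts at the
  extracted trajectory and ends at the beam-state schedule and its accuracy
  metrics.
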