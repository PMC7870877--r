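---
title: "Pressure-volume loop analysis under acute load interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pressure-volume loop analysis under acute load interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvload)
```

## The scientific problem

The end-systolic pressure-volume relationship (ESPVR) - the regression
through per-beat end-systolic (volume, pressure) points collected while
the load on the left ventricle changes - is the classical
load-independent index of contractility: its slope is the end-systolic
elastance Ees (mmHg/mL) and its volume-axis intercept is V0 (mL).
Whether the relation is actually linear and load-independent is
contested. Under rapid afterload increases the end-systolic points
trace a visibly *biphasic* course: an initial steep limb followed by a
shallower one. `pvload` implements an analysis pipeline that treats
this explicitly - fitting both a single linear ESPVR and a *bilinear*
ESPVR whose breakpoint is found by maximizing the geometric mean of
the two segments' coefficients of determination - together with a
closed-loop hemodynamic simulator in which the two mechanisms believed
to produce the biphasic course are explicit and independently
switchable:

* **Shortening deactivation (SDA)**: rapid fiber shortening against a
  raised afterload reduces force generation. Operationally, the
  effective volume intercept of the ventricle's elastance line is an
  affine function of the afterload level, indexed by the effective
  arterial elastance Ea = Pes/SV: `V0_eff = a * Ea + b`, with a < 0.
  Raising afterload shifts the ESPVR leftward within a couple of
  beats, raising pressure generation without any ventricular dilation.
* **Frank-Starling mechanism (FSM)**: the slower, dilation-mediated
  response. Reduced stroke volume lets blood accumulate upstream, the
  central venous compartment charges, filling increases, and over
  ~5-10 beats the end-diastolic volume rises, recovering stroke
  volume.

Because every simulated recording carries a per-beat ground-truth log
(effective V0, true end-systole time, Ea), every stage of the analysis
is testable against known truth - the central design goal.

## The analysis pipeline

Given a multichannel recording at 1000 Hz (LV pressure, raw
conductance volume, aortic pressure, aortic flow, ECG):

1. **Beat segmentation** (`detect_rwaves`, `segment_beats`): beats span
   R-wave to R-wave, half-open; end-diastolic values are read at the
   beat's first sample. The detector takes strict local maxima above a
   fraction (default 0.4) of the signal's maximum amplitude with a
   200 ms refractory period - adequate for clean or synthetic ECG, not
   for pathological morphologies.
2. **Extrasystole exclusion** (`filter_extrasystoles`): beats whose RR
   deviates more than 20% from the running median (window 5) are
   removed together with the following (compensatory) beat. The rule
   replaces manual curation for reproducibility; follower removal does
   not cascade.
3. **Conductance calibration** (`estimate_alpha`,
   `calibrate_volume`): the slope factor alpha is the ratio of mean
   conductance stroke volume to mean flow-probe stroke volume over
   baseline beats (flow integrates positive samples only); the
   parallel-conductance volume Vp is an external input (saline-bolus
   estimation is out of scope). The calibrated volume is
   `(raw - Vp) / alpha`.
4. **Window selection** (`intervention_window`): starting at the
   annotated intervention onset, beats stay in the window while the
   beat-to-beat change in preliminary end-systolic pressure or volume
   exceeds 2 mmHg / 2 mL; the window closes after two consecutive
   quiet beats.
5. **Slack volume and end-systole** (`estimate_vd`, `beat_emax`):
   end-systole is the sample maximizing `P(t) / (V(t) - Vd)`; Vd is
   found by fixed-point iteration - fit the end-systolic points,
   take the line's volume intercept as the next Vd - from `Vd = 0`,
   tolerance 0.1 mL, at most 50 passes, clamped 1 mL below the
   smallest observed volume. A 0.5 mL guard band on the denominator
   keeps the elastance finite.
6. **Fits** (`fit_linear_espvr`, `fit_bilinear_espvr`, `fit_prsw`):
   ordinary least squares throughout (closed-form normal equations;
   `stats::lm` serves as the independent oracle in the test suite).
   The bilinear fit enumerates every contiguous split with at least 3
   points per segment *in beat order* - the phases are temporal, not
   volumetric - and keeps the split with the highest geometric mean
   r², earliest on ties. Both models are always computed; the reported
   model follows the intervention kind (linear for preload, bilinear
   for afterload), as in the source analyses.
7. **Indices and landmarks** (`beat_indices`, `phase_table`): Ped/Ved
   at the R-wave, Pes/Ves from the maximal-elastance point,
   SV = Ved - Ves, SW as the shoelace area of the closed PV loop,
   Ea = Pes/SV, dP/dtmax as the maximal centered difference. Landmarks
   a/b/c (window start, breakpoint, window end) are summarized with
   one neighbor beat averaged on each side.

Before segmentation the hemodynamic channels pass a second-order
zero-phase Butterworth low-pass at 30 Hz (`lowpass_channels`).
Pressure and conductance signals are physically band-limited well
below that corner, so the filter removes broadband sensor noise
without touching waveform morphology; it can be disabled. Without it,
sample noise biases the maximal-elastance search toward favorable
noise excursions and inflates the volume-axis extrapolation error of
the fits.

## The simulator

A four-compartment closed loop integrated with classical fixed-step
RK4 at the output rate (1 kHz): time-varying-elastance left ventricle,
three-element Windkessel (characteristic resistance Rc, compliance Ca,
peripheral resistance Rp), a large peripheral venous reservoir (Cv),
and a small central venous compartment (Cvc) between the venous-return
resistance and the mitral valve. Ventricular pressure is

    P(t) = e(t) * Ees * (V - V0_eff) +
           (1 - e(t)) * A * (exp(B * (V - V0d)) - 1)

with a double-Hill activation `e(t)` normalized to peak at 1. Valves
are ideal diodes with series resistance. Because the four compartment
derivatives sum to zero at every RK4 stage, total blood volume is
conserved to rounding error - a standing sanity check.

The fourth (central venous) compartment deserves a note: a
three-compartment loop with a single venous pool cannot express the
Frank-Starling phase at all, because any arterial pressurization
*withdraws* volume from the only venous store, so an afterload step
never raises filling pressure and the ventricle cannot dilate. The
small central compartment is the minimal venous-backup state: a
transient output deficit charges it over a few beats and preload
adapts - the textbook venous-return picture.

### The SDA update rule

`V0_eff` is updated once per beat from the *previous* beat's Ea via
`sda_v0()` (one-beat delay, no within-beat algebraic loop), with an
optional relaxation gain. Crucially, the update is **active only while
the arterial load is settling**: during an initial equilibration
window and for beats within (or up to `sda_post_beats` after) a
scheduled change of an afterload parameter (Rp or Rc). While the
afterload is held - and during purely venous (preload) maneuvers -
`V0_eff` holds constant.

This gating is a deliberate design decision, and the reasoning is
worth recording. Driving the law from the measured Pes/SV on *every*
beat closes a feedback loop (Ea -> V0 -> Pes -> Ea) that (a) becomes
unstable whenever SV falls below |a|*Ees (~29 mL at defaults, i.e.
every deep vena-cava occlusion), and (b) makes V0 drift continuously
through both intervention types, which biases the preload-run slope
far from Ees and bends the afterload run's second phase off its line.
The physiological reading - and the one consistent with preload
sweeps remaining almost perfectly linear in real animals - is that
the deactivation state is set by the afterload the ventricle actually
faces during ejection, which is constant while the occluder is held.
With the gated rule the simulator reproduces, simultaneously: linear
preload ESPVRs recovering Ees and the current effective V0; a steep
first afterload phase (fitted slope roughly 2-3x Ees); a second phase
ascending the frozen-V0 line with slope Ees while the ventricle
dilates; and a leftward-shifted linear ESPVR for preload reductions
at elevated afterload.

### Protocols and defaults

Three intervention protocols mirror the study design: `vload_normal`
(venous-return resistance ramped x15 at 8 s, released at 15 s - a
7 s occlusion), `pload` (peripheral resistance ramped x2.8 over 1.5 s
at 8 s and held), and `vload_high` (the afterload ramp at 4 s, then
an occlusion from 10-17 s on the held afterload). Baseline
annotations start at 3 s so calibration beats reflect the
pre-intervention steady state.

Defaults describe a healthy ~50 kg pig at heart rate 80: Ees 1.2
mmHg/mL, V0 10 mL, EDPVR `0.7 * (exp(0.035 (V - 40)) - 1)` mmHg
(end-diastolic pressure ~8-10 mmHg at Ved ~110-117 mL), Rc 0.06 /
Rp 0.65 mmHg s/mL, Ca 3 mL/mmHg, Cv 60, Cvc 15 mL/mmHg, Rm 0.01 /
Rv 0.08 mmHg s/mL, total stressed volume 1300 mL. These yield Pes
~75-90 mmHg, SV ~50-58 mL, Ea ~1.4-1.6 mmHg/mL at baseline. The SDA
law defaults to the afterload dependence `V0 = -24.2 Ea + 23`
(mL per mmHg/mL; mL). Measurement noise defaults: 0.5 mmHg on
pressures, 1 mL on conductance volume, 1 mL/s on flow, 0.02 mV on
ECG, all white Gaussian, seeded per run. Extrasystoles (premature
beat at 0.65 RR with 0.7 activation amplitude, partially compensatory
pause at 1.15 RR) are injected by the beat clock only on request -
they exist to exercise the exclusion filter.

What the generator does *not* emulate: baroreflex (hence no
ascending/descending-site differences), coronary perfusion effects,
the Anrep effect, respiration, catheter motion artifacts, ischemia,
or pink (1/f) sensor noise. Passing tests therefore certify the
pipeline's correctness on data whose beat morphology and noise are
idealized, not its robustness to pathological in vivo signals.

## A worked cohort

```{r cohort, eval = FALSE}
co <- simulate_cohort(cohort_config(n_animals = 10, repeats = 3,
                                    master_seed = 1))
aggregate_fit_table(co)   # Ees and r2 by intervention x fit type
v0_ea_analysis(co)        # pooled V0-vs-Ea line + correlation table
```

Between-animal dispersion: 10% lognormal CV on Ees and the vascular
parameters, 2 mL SD on V0, 5 bpm SD on heart rate, and 20% CV on the
afterload ramp magnitude (occluders differ between animals, are fixed
within one). Each run gets an independent sub-seed drawn from the
master seed; identical master seeds give bit-identical tables.

## Numerical and statistical choices

* Fixed-step RK4 at 1 ms matches the 1 kHz output grid and sidesteps
  event detection at valve switching; halving the step changes
  beat-level Pes/Ves by well under 0.5%.
* Ties in the maximal-elastance search break to the earliest sample;
  ties in the split search break to the earliest split (determinism).
* Parallel bilinear segments fall back to the midpoint between the
  adjoining points, flagged.
* Non-positive ESPVR or PRSW slopes are flagged, not raised -
  near-horizontal preload-recruitable stroke work is an expected
  outcome under pure afterload loading.
* `min_seg = 3` points per bilinear segment: r² of a two-parameter
  line is trivial below three points; `n_points` is always reported
  alongside any r².
* The pooled V0-vs-Ea law is estimated per animal (median over
  repeats) with the second-phase V0 read off the phase-2 centroid at
  the animal's *preload-run* slope - the model's own premise that the
  second phase shares the preload slope - against the single-beat Ea
  at the breakpoint, which is the afterload level that set the
  deactivation state. Reading V0 from the free bilinear fit instead
  (selectable) extrapolates a short noisy segment ~90 mL to the
  volume axis and roughly triples the per-run scatter.

## Known limitations

* The V0-vs-Ea recovery is structurally attenuated: the deactivation
  state locks at the end of the first afterload phase, where the
  across-animal spread of Ea is two to three times narrower than at
  the settled state. With 10 animals the recovered slope is unbiased
  in the median but its seed-to-seed scatter is of the same order as
  a +/-20% band; individual cohorts can land outside it.
* Vd estimation assumes genuine load variation inside the window; two
  identical beats are rejected as degenerate rather than silently
  fitted.
* The R-wave detector is for clean fiducials; it makes no attempt at
  pathological QRS morphologies.
* Problem sizes used throughout the tests - 20 s runs, 10-animal
  cohorts with 1-3 repeats - were chosen as the smallest sizes at
  which every mechanism is identifiable.
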