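---
title: "Validating foot-worn inertial gait measures against optical capture: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating foot-worn inertial gait measures against optical capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a stroke, retraining foot elevation (a flat or toes-down foot strike)
and forward propulsion is a central goal of gait rehabilitation. In the
laboratory both are measured with an optical motion capture system (OMCS)
and instrumented force plates; at home only wearable sensors are practical.
`strideval` implements the full analysis needed to judge whether a single
foot-dorsum inertial measurement unit (IMU) can stand in for the laboratory
reference:

* estimate the **foot strike angle** (FSA) — the sagittal angle between the
  sole and the surface at initial contact, positive for a toes-up (rearfoot)
  strike — independently from the IMU and from heel/toe markers;
* compute eight candidate **indicators of forward propulsion** (foot and
  shank angle at terminal contact, maximal foot/shank angular velocity and
  acceleration during stance, maximal horizontal shank acceleration, stride
  length) from both systems;
* quantify **agreement** stride by stride and within subjects
  (Bland–Altman, ICC(3,1), repeatability coefficient) and **association**
  with the force-plate propulsion measures (Pearson correlation tables).

Because the pipeline must be testable without laboratory recordings, the
package ships a synthetic treadmill-gait generator that produces mutually
consistent marker, IMU and force-plate streams with exact per-stride ground
truth.

## Measurement model

### Event detection

Optical events follow the coordinate-based treadmill method: initial
contact (IC) is the zero crossing of the heel marker's anterior–posterior
velocity in the posterior direction (the heel's forward-most point), and
terminal contact (TC) the zero crossing of the toe marker's AP velocity in
the anterior direction (the toe's rearmost point). Inertial events use the
foot gyroscope and accelerometer: **mid-swing** is the prominent positive
peak of the mediolateral angular velocity; **IC** is the first zero
crossing of that channel after mid-swing; **TC** is the peak
gravity-removed vertical acceleration between consecutive mid-swing events.
The **foot-flat phase** of one side is bounded by the contralateral TC and
the contralateral mid-swing — while the other leg swings past, the
ipsilateral sole rests flat on the belt.

For the optical branch, mid-swing (needed only to anchor the foot-flat
window) is detected with the same peak detector applied to the
differentiated marker-based foot angle, so the two branches stay fully
independent until their IC events are paired by greedy nearest-neighbour
matching (candidates closer than half the median stride time).

### Angles and calibration

The marker-based foot angle is `atan2(vertical, walking-direction)` of the
toe-minus-heel vector; the IMU foot angle is the sensor's Euler pitch.
Both are zeroed on the foot-flat windows of the first ten strides: the
subtracted mean is, for the IMU, exactly the mounting tilt of the sensor on
the dorsum of the foot. The FSA of a stride is the calibrated angle at that
stride's own-system IC (sample lookup, no interpolation). Because the
calibration subtracts any constant, the FSA is invariant to the mounting
tilt — a property the test suite checks to numerical precision.

The optical shank angle is `atan2` of the knee-minus-ankle vector (a
vertical shank reads 90°). The shank sensor's Euler pitch is re-referenced
so its mean over the same foot-flat windows equals 90°: the shank crosses
vertical near mid-stance, so this removes the arbitrary shank mounting
offset while leaving the within-stride dynamics (all downstream consumers —
TC values, stance maxima, correlations — are offset-insensitive anyway).

### Propulsion

The anterior–posterior ground reaction force of a stance is windowed by the
optical (gold standard) events; the braking-to-propulsion transition (BPT)
is the **last** negative-to-positive zero crossing before TC (robust to
early-stance oscillation). Propulsion AUC is the trapezoidal integral of
the body-weight-normalized AP force from BPT to TC (`dt = 1/fs_force`,
units BW·s); the propulsion peak is the window maximum (BW). A stride
enters the propulsion analysis only if one foot was on a single plate:
the own plate must carry at least 0.3 body weight throughout mid-stance
(35–65 % of stance, which is guaranteed single support), no foreign load
above the crosstalk threshold (default 20 N, a typical plate noise floor)
may appear on it during the stride's swing, and during double support the
contralateral plate must be demonstrably loaded.

### Agreement and correlation statistics

Differences are IMU − OMCS. Bland–Altman reports the mean difference, the
sample SD (n−1) and limits of agreement `mean ± 1.96·SD` (the exact normal
multiplier, no small-sample t correction). The repeatability coefficient is
`1.96 · sqrt(mean(d²))` — 1.96 times the RMS of the differences — which is
monotone in the systematic bias and reduces to `1.96·SD` only for unbiased
differences. ICC(3,1) is the two-way mixed, single-measure *consistency*
intraclass correlation computed from the ANOVA mean squares,
`(MS_rows − MS_error) / (MS_rows + MS_error)` for two raters, with its 95 %
interval from the F-distribution bounds; the consistency form is used
because it is insensitive to a constant inter-system bias. The
within-subject scope repeats the Bland–Altman/RC computation per subject
and summarizes the per-subject values as mean ± SD (n−1 across subjects).

Pearson correlations (with two-sided p from the t transform, n−2 df) are
computed for each indicator × system × propulsion target, pooled across
eligible strides and, in the within-subject scope, per subject and then
averaged. Magnitudes are banded weak (< 0.5), moderate (0.5–0.75), good
(0.75–0.9) and excellent (≥ 0.9), on |r| since negative correlations are
banded by size; interior boundaries are closed on the left.

## The synthetic gait generator

One stride of one side is parameterized by its duration `T` (Gaussian,
default 1.2 ± 0.03 s, draws clamped at ±2.5 SD), stance fraction `c`
(default 0.70), the per-stride FSA (default 7 ± 1.2°), the plantarflexion
depth at TC (15 ± 1.5°) and the propulsive peak (0.20 ± 0.03 BW). The two
sides alternate with a half-cycle phase shift. The defaults model slow
hemiparetic treadmill gait at about 1 m/s: a modest toes-up strike, reduced
push-off, and a long double-support time (stance 70 % of the cycle) — the
population and condition in which foot-strike feedback is clinically
relevant. Subject-level variation (`cohort_profiles()`) draws per-subject
means around these values.

### Foot pitch

The sagittal foot pitch of a cycle is piecewise polynomial and twice
continuously differentiable, with continuous jerk at every interior join:

1. **Strike descent** from the FSA to zero: the minimal-jerk profile for
   "start at A with zero rate, end at zero with zero rate and curvature",
   whose bang-bang jerk switch is smoothed by a linear ramp. Its duration
   is set per cycle so the plateau is reached just before the contralateral
   TC opens the foot-flat window.
2. **Foot-flat plateau**: identically zero until 60 % of stance.
3. **Push-off blend** to `−pushoff` at TC: a degree-6 polynomial whose
   value, rate, curvature *and jerk* vanish at the plateau join, augmented
   to minimize its peak jerk.
4. **Swing arc** back to the next stride's FSA: a quintic with the jerk at
   TC matched to the push-off blend, a jerk-neutral `u⁴(1−u)⁴` term that
   places the angular-velocity maximum (mid-swing) in the first 55 % of the
   swing, and a short degree-7 "adapter" over the final 80 ms that ramps
   the jerk continuously into the next descent without altering the FSA,
   the IC zero crossing, or its slope.

This smoothness budget is deliberate: at 100 Hz, numerically
differentiating the Euler pitch must reproduce the gyroscope channel to
within 1 deg/s, and zero-phase filtering must not displace events. Both
requirements bound the admissible jerk (a 7–10° strike descent completed in
~0.2 s is already close to the limit), which is why the generator keeps the
pitch C³ at joins and uses minimal-jerk shapes rather than simple cosine
blends.

Ground-truth IC is the descent start (where the gyro crosses zero with
symmetric slope), TC the stance end, and mid-swing the analytic maximum of
the swing rate (located via the polynomial root structure) — so every
detector can be scored stride by stride against exact times.

### Markers, accelerations, forces

The heel AP velocity is a C¹ cubic-Hermite spline with zeros exactly at IC
(crossing anterior→posterior) and TC (posterior→anterior), a mid-stance
plateau at `−belt_speed`, and zero net displacement per cycle (so the true
stride length is `belt_speed × T`). The toe is the heel plus
`foot_length · (cos θ, sin θ)` — a rigid foot — which makes the
marker-derived segment angle equal the pitch exactly and lets the toe
inherit its TC zero crossing from the heel (pitch rate and curvature vanish
at TC). Ankle and knee are fixed points in the foot and shank frames; the
shank pitch is a two-harmonic oscillation about vertical whose phases put
its foot-flat-window mean at 90°.

The foot sensor's vertical acceleration is three raised-cosine lobes per
cycle — the push-off peak exactly at TC (the landmark the inertial TC
detector uses), a swing counter-lobe, and a landing lobe of half the
push-off amplitude — whose integrals close the heel's vertical velocity and
position over the cycle; heel height is their exact double integral. The
shank's global-frame acceleration is the analytic second derivative of the
knee-minus-ankle vector, which is precisely what the optical branch
differentiates numerically. Sensor-frame accelerations add gravity rotated
by the (tilted) segment attitude. Vertical ground reaction force is a
double-bump profile (`1.1 sin(πu) + 0.28 sin(3πu)` body weights over
stance); the AP force is a braking half-sine followed by a propulsive
half-sine joined at the BPT (default 50 % of stance), so the propulsion
truth is closed-form: `AUC = 2·A·D/π` for amplitude A and duration D.

Two controlled imperfections can be injected: a fraction of stances may
land on the contralateral plate (exercising the eligibility filter, with
the affected neighbouring strides flagged ineligible in the truth), and a
per-stride, gait-phase-locked perturbation of the Euler-pitch output that
vanishes during foot-flat and equals its drawn value exactly at IC. The
latter emulates the transient error of a sensor-fusion attitude estimate
around heel strike: it perturbs only the orientation output, not the raw
gyroscope, and — because foot-flat calibration removes constants but not
phase-locked transients — it injects a controllable inter-system FSA
difference with known mean and SD.

All randomness is clamped Gaussian per stride, drawn once from the seed;
identical arguments give bit-identical trials.

### What the generator does not emulate

Sagittal-plane motion only (no frontal/transverse kinematics, no
out-of-plane marker noise structure); no soft-tissue artifact, marker
occlusion or gap filling; additive i.i.d. Gaussian sensor noise rather
than colored or drifting noise; no magnetometer or sensor-fusion dynamics
beyond the phase-locked orientation transient; no self-paced belt-speed
dynamics; no turning, stair or overground gait. Passing the test suite
therefore shows that the algorithms are correct implementations with the
stated accuracy on well-behaved treadmill-like signals — not that a
particular hardware set-up reaches the same accuracy on real patients.

## Numerical choices

* **Filters**: zero-phase (forward–backward) Butterworth low-pass; second
  order at 15 Hz for angular velocity and markers, 17 Hz for acceleration,
  fourth order at 20 Hz for forces. Zero-phase filtering avoids the phase
  lag that would bias event timing between systems, at the cost of squaring
  the magnitude response (a sinusoid at the cut-off is attenuated to 0.5).
  Edge effects are controlled by odd-reflection padding (3 × order) plus
  steady-state initialization of the filter at the boundary value, so
  constants pass exactly.
* **Differentiation**: central differences in the interior, one-sided at
  the edges; angular acceleration is the derivative of angular velocity
  (the first-derivative operator applied twice). No extra smoothing — the
  channel filters have already been applied.
* **Zero crossings** are localized by linear interpolation and rounded to
  the nearest sample (events are reported at the 100 Hz motion rate);
  sub-threshold jitter crossings are suppressed by hysteresis (markers:
  0.1 m/s) and peak guards (mid-swing: prominence ≥ 50 deg/s, separation
  ≥ 0.4 s). Ties at equal acceleration maxima resolve to the earliest
  index, for determinism.
* **Quadrature**: trapezoidal, at the native 1000 Hz force rate; the
  closed-form half-sine integral is reproduced to well under 0.1 %.
* **Stride length** on a treadmill is heel displacement between consecutive
  ICs plus belt travel over the same interval; the belt speed comes from
  trial metadata and its absence is a named error.

## Design choices where the problem was genuinely open

* **Which events bound foot-flat**: both bounding events are read as
  contralateral-side events (TC, then mid-swing). An ipsilateral reading
  cannot produce a flat-on-ground window, since the ipsilateral TC ends
  stance.
* **Repeatability coefficient**: defined as 1.96 × RMS of the differences.
  With a mean difference m and SD s this equals `1.96·sqrt(m² + s²)` — the
  definition under which the worked-example inputs (m = 1.4°, s = 2.3°)
  give 5.3°, and under which adding a systematic bias can never shrink the
  coefficient.
* **ICC form**: consistency rather than absolute agreement, because the
  stride-level question ("do the systems rank strides identically?") is
  bias-tolerant, and the calibration already absorbs constant offsets.
* **IMU stride length**: a single foot sensor cannot measure displacement
  without drift-prone double integration; the stride-length indicator is
  computed from the heel marker and belt travel for both branches, each
  branch contributing its own IC times.
* **Propulsion target**: computed once from the force plates using the
  optical stance windows and shared by both systems' correlation tables —
  the force plate is the reference instrument in either case.
* **Band boundaries**: closed on the left (0.5 is moderate, 0.75 is good,
  0.9 is excellent), banding on |r|.

## Problem sizes used by the tests and the acceptance script

The packaged checks run a noiseless 12-subject × 50-stride cohort for
stride-level truth recovery, a 12 × 260-stride cohort (≈ 6 200 strides)
for the pooled agreement statistics under an injected inter-system
discrepancy of 1.4 ± 2.3°, and a 4 × 250-stride cohort (≈ 2 000 strides)
for correlation recovery with an injected indicator–propulsion correlation
of 0.8, plus per-operation unit and property tests on small analytic
fixtures. These sizes give sampling errors comfortably below the asserted
tolerances while keeping a full run in a few minutes on one CPU.

## Known limitations

* The detectors assume treadmill walking with a periodic, alternating gait;
  they are not suitable for turning, stopping, or overground bouts.
* Eligibility decisions at the first and last strides of a recording can be
  conservative (missing contralateral context marks a stride ineligible).
* The within-subject correlation scope requires at least two subjects with
  enough eligible strides; degenerate (zero-variance) indicators are
  dropped per subject rather than imputed.
* The synthetic cohort's ICC depends on the chosen between-stride FSA
  variance relative to the injected discrepancy SD; it is reported as
  computed, not calibrated to any external value.
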