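# strideval

Stride-level validation of foot-worn inertial sensors against optical
motion capture, for treadmill gait analysis in rehabilitation research.

## What it does

Clinicians retraining gait after stroke care about two quantities that are
hard to measure outside the laboratory: the **foot strike angle** (FSA, the
sagittal angle between the sole and the surface at initial contact;
positive = toes-up) and **forward propulsion** (the propulsive part of the
anterior–posterior ground reaction force). `strideval` implements the full
pipeline needed to test whether a single foot-dorsum IMU can replace the
laboratory reference:

* **Event detection**, independently per system: optical initial/terminal
  contact from heel/toe anterior–posterior velocity zero crossings
  (coordinate-based treadmill method); inertial mid-swing, IC and TC from
  the gyroscope and gravity-removed vertical acceleration.
* **Kinematics**: foot and shank angles
  (`atan2(vertical, walking-direction)` of marker segments; Euler pitch for
  the IMU), foot-flat calibration that recovers the sensor mounting tilt,
  per-stride FSA, stance-phase maxima of angular velocity/acceleration,
  horizontal shank acceleration, treadmill stride length.
* **Kinetics**: braking-to-propulsion transition, body-weight-normalized
  propulsion AUC (`∫ GRF_AP dt` from BPT to TC) and peak, and the
  one-foot-per-plate eligibility filter.
* **Statistics**: Bland–Altman bias and 95% limits of agreement
  (`mean ± 1.96·SD`), repeatability coefficient (`1.96·RMS` of the
  differences), ICC(3,1) (two-way mixed, single measure, consistency, with
  F-based CI), and Pearson correlation tables of eight candidate
  propulsion indicators × two systems × two targets, stride-by-stride and
  within-subject.
* **Synthetic gait generator**: mutually consistent marker, IMU and
  force-plate streams for a parameterized walker with exact per-stride
  ground truth (event times, FSA, propulsion AUC/peak, stride length,
  eligibility), so every stage is testable without any recording.

## Worked example

Simulate a 4-subject cohort in which the inertial FSA carries a known
per-stride discrepancy of 1.4 ± 2.3° against the optical reference, run
the full validation, and print the report:

```r
library(strideval)

base <- gait_profile(fsa_bias_mean = 1.4, fsa_bias_sd = 2.3)
profiles <- cohort_profiles(4, seed = 2, base = base)
rep <- run_validation(run_config(profiles, n_strides = 40, seed = 2))
print(rep)
#> <validation_report>
#>   328 strides included for stride-by-stride validity analysis.
#>   ICC(3,1) = 0.81, 95%CI: [0.77; 0.84] (good).
#>   Mean IMU-optical FSA difference 1.3 degrees, 95% limits of agreement -3.5 to 6.1 degrees.
#>   Repeatability coefficient 5.4 degrees.
#>   Within-subject: mean difference 1.3 (SD 0.3) degrees, mean repeatability coefficient 5.4 (SD 0.3) degrees.
#>   257 of 328 matched strides eligible for propulsion analysis.
```

The recovered bias (1.3°) and limits of agreement sit at the injected
values up to sampling error; strides where both feet loaded one force
plate were excluded by the eligibility filter. The same report object
carries the stride table, the per-subject agreement rows, and the
indicator-vs-propulsion correlation grid (`rep$correlations`).

Single pieces work standalone, e.g. the agreement worked example from
summary statistics:

```r
limits_of_agreement(1.4, 2.3)   # -3.108  5.908
rc_from_summary(1.4, 2.3)       # 5.28
```

or one synthetic stride of the foot-pitch model:

```r
w <- foot_pitch_waveform(gait_profile(), list(stride_time = 1.2, fsa = 10))
w$angle[1]                 # 10  (the FSA, realized exactly at initial contact)
attr(w, "tc_time")         # 0.84 s   (terminal contact)
attr(w, "midswing_time")   # 1.002 s  (swing-phase angular-velocity maximum)
```

A thin command-line wrapper is installed under `inst/cli/strideval.R`
(`simulate` and `run` subcommands over a YAML configuration).

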