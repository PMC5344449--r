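---
title: "Models and methods behind nirstroop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirstroop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirstroop)
```

`nirstroop` implements a complete analysis chain for multichannel
continuous-wave fNIRS recordings from block-design conflict (Stroop-type)
paradigms, together with a forward simulator that makes every stage testable
against known ground truth. This vignette documents the models, the
parameters that matter, the numerical choices, and the limits of what the
simulations can show.

## The paradigm being modeled

A run consists of twelve 15 s task blocks alternating with 15 s rest
(6 minutes total). Each block holds four trials at a 3.75 s inter-stimulus
interval; blocks are congruent-dominant or incongruent-dominant (six of
each), and each block contains exactly one randomly positioned *oddball*
trial of the opposite congruency, preventing single-condition repetition
effects. Two tasks are modeled: a gesture/word task (spoken "yes"/"no"
against affirmative or negative gestures) and a two-color word Stroop task.
Trials therefore carry a task label, a congruency label, and nuisance
attributes (actor gender, gesture type) that the simulator randomizes but
to which it attaches no hemodynamic effect.

## Acquisition model and the modified Beer-Lambert law

The simulated instrument has 30 emitters and 29 detectors at nominal 30 mm
separations forming 98 measurement channels, sampling at 27 ms, with three
laser wavelengths (780, 805, 830 nm; 805 nm is near the isosbestic point).
The bundled montage is a stylized, clearly synthetic stand-in for the
study-specific cap: a 5 x 11 optode band wrapped around a cylindrical head
model plus a 2 x 2 vertex patch, which reproduces the channel count,
spacing and rough frontal/temporal/parietal coverage but not the true
layout.

Optical density changes relate to chromophore concentration changes
linearly through the modified Beer-Lambert law,

$$\Delta OD(\lambda, t) = \left[\varepsilon_{HbO}(\lambda)\,\Delta HbO(t) +
\varepsilon_{HbR}(\lambda)\,\Delta HbR(t)\right] \cdot L,$$

with $L$ an effective pathlength. `mbll_invert()` solves this per channel
and time point by least squares over the wavelengths (with three
wavelengths and two chromophores, the normal-equations solution);
`forward_mbll()` is its exact inverse and drives the simulator. Extinction
coefficients come from the standard Gratzer/Kollias tabulation. Because the
differential pathlength factor of the original instrument is unknown, $L$
defaults to 1 and all concentrations are *relative* (µM-equivalent) —
sufficient for GLM inference, which is scale-invariant per channel.

## The synthetic-data generator

`generate_hemo_truth()` builds, per channel,

HbO = (nominal amplitude + subject deviation) x HRF-convolved condition
regressors + systemic oscillations + slow drift + white noise,

and HbR as −1/3 of the noiseless HbO component plus independent noise of
the same SD (deoxyhemoglobin falls during activation and is typically
smaller; the ratio is configurable). Key defaults, chosen once as
field-realistic values and not revisited:

| parameter | default | meaning |
|---|---|---|
| `noise_sd` | 1 µM-eq | white measurement noise per channel |
| `response_sd` | 1 µM-eq | between-subject SD of each channel x condition amplitude |
| cardiac / resp / Mayer | 0.2 / 0.3 / 0.4 µM-eq at 1.1 / 0.25 / 0.095 Hz | global oscillations, shared across channels with gains ~ N(1, 0.1) |
| `drift_amp` | 0.5 µM-eq | slow channel-specific baseline wander |
| `hbr_to_hbo_ratio` | −1/3 | HbR response relative to HbO |

The between-subject component `response_sd` deserves emphasis: it is drawn
independently per channel and condition for each subject and is what gives
group-level t statistics realistic magnitudes. Without it, all simulated
subjects share one response and group t values are limited only by
measurement noise, so even a percent-level leakage of a planted effect
into a neighboring channel becomes "significant". The original study's
effect sizes in concentration units are not recoverable from the
publication, so planted amplitudes are free parameters of each experiment.

Reaction times are lognormal (positive, right-skewed) with a per-subject
offset; incongruent trials are delayed by a configurable `delta`
(defaults: 40 ms for the gesture task, 106 ms for color). Correctness is
Bernoulli at the task's accuracy (98.2% / 98.7%).

All generators are deterministic functions of `(config, seed)`; per-subject
seeds are derived arithmetically from the study seed and stay within
32-bit range.

## Preprocessing

The stage order is fixed and recorded in the run provenance:

1. **Dead-channel QC** — a channel is excluded when the RMS of its raw
   optical-density trace exceeds 10x the mean RMS over channels.
2. **MBLL conversion**; the analysis signal defaults to deoxyhemoglobin
   (less contaminated by systemic physiology), sign-flipped so that
   activation maps to positive effects.
3. **Wavelet detrending** — the least-squares line is removed, then a
   periodized orthogonal DWT (Daubechies-4 by default; Haar available)
   zeroes the approximation band below ~0.01 Hz. Line removal keeps the
   periodic boundary continuous, so the wavelet's edge effects stay local.
4. **Zero-phase low-pass** at 0.1 Hz (4th-order Butterworth, forward and
   backward), mean-centered and reflection-padded against edge transients.
   Zero-phase filtering avoids distorting HRF latency.
5. **PCA spatial filter** — spatial principal components of the channel
   covariance; components whose spatial-uniformity score
   $|\mathrm{mean}(v)|\sqrt{n_{ch}}$ exceeds 0.7 are eligible as *global*
   (systemic) components, and the top `k = 1` of them is projected out.
   The uniformity gate is essential: after the 0.1 Hz low-pass the largest
   variance component can be a spatially localized task response, which a
   blind top-k filter would delete. A perfectly global component scores
   ~1, a random direction ~0.1, so 0.7 separates them cleanly.
6. **Downsampling** 10-fold (27 ms → 270 ms), the low-pass having served
   as the anti-alias filter. (The source description of the effective rate
   is internally inconsistent — 27 ms x 10 is 0.27 s, not 0.9 s — so the
   literal 10-fold factor is used and is configurable.)

A cryptic description of "detrending with the RMS of the residual after
HRF deconvolution" is implemented as what it syntactically is: a QC metric
(`hrf_residual_rms()`), not a transformation — wavelet detrending is
separately and clearly specified.

## First-level GLM

`build_design()` places one boxcar per trial (default duration 1.5 s —
the stimulus epoch; the source does not state stick vs boxcar, so the
duration is configurable) into one regressor per task x congruency
condition; oddballs count toward their own congruency (a switch allows
excluding them). Regressors are convolved with a canonical double-gamma
HRF parameterized by its modes (peak 6 s, undershoot 16 s, ratio 6:1,
unit peak) on a 50 ms internal grid and sampled at the frame times.
Condition columns are normalized to unit single-trial peak, so a beta is
the peak single-trial response in the signal's own units. `fit_glm()` is
ordinary least squares per channel; no prewhitening and no HRF
derivatives, mirroring the original analysis. Contrast presets: `"I>C"`
(incongruent − congruent, summed over tasks) and `"G>C"` (gesture −
color, summed over congruencies).

## Group inference

Per-channel first-level contrasts are the group-level currency (running
the GLM per channel is mathematically equivalent to the source's opaque
reshaped-image formulation, whose printed cluster sizes are inconsistent
with a 64-voxel volume). Subjects' channel positions are registered to the
component-wise **median channel coordinate** with inverse-distance
weighting over each subject's `k = 4` nearest channels (the original
"non-linear interpolation" is named but never specified; IDW is the
approximation). Contrasts are then interpolated to a 4 mm MNI grid by a
normalized Gaussian kernel (FWHM 15 mm) over channels within 20 mm; the
mask is the 20 mm channel-support shell. These scales reflect
scalp-projected fNIRS sensitivity and are configurable.

Significance uses the study's **dual criterion**:

* voxel-wise: one-tailed one-sample t (df = n−1), uncorrected p < 0.001,
  18-connected cluster extent ≥ 70 voxels (the calibrated corrected
  threshold);
* channel-wise: a spatially corresponding channel (within 20 mm of the
  cluster) must reach p < 0.05 across 98 channels.

Findings meeting only the channel criterion are labeled "active", not
significant. One-tailed tests follow the published t/p/df combinations,
which match the one-tailed values.

### Sign-flip Monte Carlo calibration

`signflip_mc()` estimates the familywise false-positive proportion of any
(cluster size, voxel p) rule: each permutation independently multiplies
every subject's volume by ±1 (valid under a symmetric null), recomputes
the group t-map, and records whether any cluster of the given size
survives. Sign flips leave per-voxel sums of squares invariant, so each
permutation costs one matrix-vector product plus connected-component
labeling (via `igraph`) at each threshold. An exhaustive mode enumerates
all $2^n$ assignments for small n and is verified in the tests against an
independent flood-fill enumeration oracle.

`cluster_fpr_calibration()` is the packaged twin of the published
calibration table: 30 null subjects of iid standard-normal channel noise,
interpolated to the default grid, 1000 permutations. With the default
geometry it reproduces the saturation cell at (size ≥ 10, p < 0.05)
(0.999 vs a printed 1) and the entire size ≥ 10 row (0.220 vs 0.2187 at
p < 0.001; 0.026 vs 0.0205 at p < 0.0001), and the table is monotone in
both directions. Down the extent column the simulated rates decay more
slowly than the published ones — (size ≥ 70, p < 0.001) computes to ~0.10
against a printed 0.0495 — indicating the published maps carried less
spatial smoothness per voxel than the default 15 mm kernel on a 4 mm grid
produces. Since neither the true voxel size nor the smoothness of the
original interpolated data is recoverable from the publication, the
package keeps the stated defaults rather than tuning them to the printed
value, and documents the discrepancy. Users with instrument-specific
knowledge can recalibrate with their own `kernel_fwhm`/`voxel_size`.

## Behavioral analysis

Gesture stimulus onsets are the median of independent rater annotations
per video (`gesture_onset()`). Reaction-time statistics aggregate
subject-first: condition means per subject, then group mean and SEM across
subjects — the aggregation under which the one-tailed paired t-test
(`paired_t_one_tailed()`, `t = \bar d / (s_d/\sqrt n)`, df = n−1) is
valid. Incorrect trials are included by default (the source does not state
an exclusion rule; a flag excludes them), and oddballs count toward their
own congruency, consistent with the GLM.

## What the simulations do and do not show

The generator emulates: the block/trial structure with oddballs, HRF
dynamics, multi-wavelength optics, global systemic oscillations, drift,
white noise, dead channels, montage jitter across subjects, between-subject
response variability, and RT interference. It does **not** emulate: motion
artifacts, scalp/superficial hemodynamics distinct from cerebral ones,
spatially correlated (non-global) physiology, non-Gaussian noise, or any
real anatomical variation in optode-to-cortex coupling. Passing tests
therefore demonstrate the correctness and calibration of the *procedures*
under the stated generative model, not the reproduction of the original
group maps, which would require the original recordings.

End-to-end verification runs the full chain — simulated optical densities
through preprocessing, GLM, registration, and the dual criterion — with a
planted gesture effect (3x noise SD in HbO, i.e. 1x noise SD on the
analyzed deoxy signal) in five contiguous right-temporal channels across
31 synthetic subjects, and requires the planted region to emerge as a
significant finding. The companion null check (no significant finding in
≥95% of 20 seeds) runs at the subject contrast-map level: the dual
criterion consumes contrast maps, so nulls generated there exercise
exactly the inferential machinery while avoiding a twenty-fold repeat of
the simulation stages that the planted arm already covers.

Problem sizes used throughout the test-suite were chosen to characterize
each property well at desk scale: 1000 permutations for the calibration
grid, 1000 random fixtures for the dead-channel rule, 100 seeds for GLM
recovery, 200 seeds for RT-delta recovery, 16-assignment exhaustive
enumeration for the sign-flip oracle.

## Numerical choices and degenerate inputs

* OD uses the log10 convention; round-trips are self-consistent.
* Zero-variance voxels in a group map are masked (`NA`) with a warning;
  clustering ignores them.
* Exact ties in nearest-channel assignment (kernel FWHM → 0) resolve to
  the lowest channel index.
* The similarity (rigid + isotropic scale) fiducial fit uses the
  SVD/Kabsch closed form with a determinant guard against reflections;
  coplanar landmark sets are rejected.
* Channels with fewer than `k` usable channels abort median registration;
  dead channels propagate as `NA` and reduce per-channel n in channel-wise
  tests.
* A paired test with identical inputs returns t = 0, p = 0.5; zero
  variance around a nonzero mean difference is an error.
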