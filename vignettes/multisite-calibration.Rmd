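---
title: "Calibrated multi-site real-time fMRI: methods and design notes"
author: "duoscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrated multi-site real-time fMRI: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoscan)
```

## Why calibration

Two scanners never produce comparable raw BOLD signals: field strength,
coils, shims and reconstruction all scale and distort the percent-signal
change, and subjects differ physiologically on top of that. A joint
real-time experiment across sites therefore needs every decision to be made
on a *relative* scale. `duoscan` implements the standard construction: a
functional localizer finds the subject's sensorimotor ROI, the maximum
mean-ROI BOLD response observed there is declared the subject's 100%
reference, and all subsequent activation is expressed as a percentage of
that individual maximum. The package exists to make the central claim —
that this calibration renders a low-amplitude site and a high-amplitude
site statistically equivalent players — a machine-checkable property of the
pipeline, exercised end-to-end on synthetic data.

## The generative model

`simulate_run()` produces a 4D series in which a voxel's intensity is

$$ I_v(t) = g\,B\,\bigl(1 + [\,w_v\,A\,e_{b(t)}\,x(t) + \varepsilon_v(t) + d(t)\,]/100\bigr). $$

* **HRF.** `canonical_hrf()` is the standard double-gamma: positive gamma
  with delay 6 s, undershoot gamma with delay 16 s, dispersions 1 s,
  undershoot ratio 1/6, peak-normalized. These are the field's canonical
  defaults; the continuous mode sits at 5 s under this parameterization.
  The kernel support is $[0, \mathrm{duration})$ sampled at the TR with the
  endpoint excluded, so a 32 s kernel contributes exactly nothing 16 TRs
  after an event — consecutive 15-scan main blocks are then analytically
  independent in the scans 8–10 window, which the parameter-recovery tests
  rely on.
* **Regressor.** $x(t)$ is the per-scan tapping indicator convolved with
  the sampled kernel, normalized by the peak of a single isolated
  unit-effort block, so a noiseless full-effort blob center attains exactly
  $A$ percent signal change.
* **Blob.** An isotropic Gaussian spatial profile with $\sigma$ equal to
  the stated radius, truncated at that radius (edge voxels keep
  $e^{-1/2} \approx 0.61$ of the center amplitude). A steeper profile makes
  edge voxels undetectable at realistic noise, which is a statement about
  the generator rather than the localizer; the chosen $\sigma$ keeps the
  whole nominal blob detectable at the tested operating point (noise SD up
  to $0.2A$). A `"flat"` plateau profile is available for analyses where
  spatial averaging must not attenuate amplitudes.
* **Noise and drift.** I.i.d. Gaussian percent noise per voxel and scan
  plus one slow sinusoid (default amplitude 0.1%, period 120 s, seeded
  random phase). No autocorrelated physiological noise, no motion, no
  susceptibility or k-space physics — so passing tests demonstrate
  correctness of the analysis chain, not robustness to artifacts real 7T
  data would add.
* **Site emulation.** Default geometries are 64×64×31 (3T) and 64×64×20
  (7T) at TR 2 s. `sample_subject_profiles()` draws 3T maximum amplitudes
  around 2.25% and 7T amplitudes around 1.6× that, emulating the observed
  ~60% group difference. The hardware gain $g$ scales raw intensities only
  and cancels exactly in every percent-change ratio;
  `scale_subject_gain()` instead scales the physiological percent fields
  (amplitude, noise, drift) jointly.

## Analysis chain and window conventions

The localizer (five 12-scan blocks; tapping at block scans 3–4) smooths
each incoming volume (3 mm FWHM separable Gaussian, border-renormalized)
and pools, block by block, the Pearson correlation between the
baseline-referenced signal (block scans 1–3) and the regressor at the
response scans (6–8, bracketing the expected HRF maximum). The running
statistic is kept as five accumulating sums per voxel, so the final map
provably equals a one-shot correlation over the same scans (tested against
a brute-force oracle at $10^{-10}$). Zero-variance voxels yield `NaN`,
never ±1. The ROI is the largest 6-connected supra-threshold
($r \ge 0.6$, configurable) cluster of at least 5 voxels; an empty result
raises a localization-failure error, the software analogue of "repeat the
measurement".

Three conventions are offered for the calibration maximum, because the
choice silently decides whether the main experiment's estimates are
unbiased:

* `"matched"` (default): per-block mean of the 3 scans starting immediately
  after tapping — the same post-tapping offsets as the main experiment's
  scans 8–10 window. The HRF-window attenuation (the 3-scan mean regressor
  is below the peak) then cancels exactly in the calibrated ratio, and a
  noiseless subject tapping at effort $e$ scores a relative activation of
  exactly $100e$.
* `"localizer"`: the localizer's own correlation window (block scans 6–8).
* `"scan_max"`: maximum over single scans; recovers the programmed
  amplitude itself but leaves the main-experiment ratio attenuated.

Percent change is referenced to the run's first baseline window (block 1,
scans 1–3) by default. The alternative per-block reference is available but
biased: the baselines of localizer blocks 2–5 sit on the previous block's
undershoot, inflating their percent change by roughly 10% and pushing the
calibration maximum upward.

The main experiment's sliding window is fixed by design: 15-scan blocks
(5 baseline, 2 tapping, 7 rest, 1 feedback; the 10 s task cue lies between
blocks, the only partition of the stated segment lengths summing to 15),
raw response = mean(scans 8–10) − mean(scans 1–5), computed per block from
only that block's data. One residual physiological bias remains: when the
*previous* block was active, its undershoot depresses the current baseline
by up to ~2% of the previous effort. This is carryover in the generative
model, not an estimator defect; recovery tests therefore quantify exactness
(better than $10^{-6}$) on blocks whose predecessor is inactive.

## Classification, tasks and exchange

Bands follow the literal reading of the protocol: relative activation
$< 30$ is insufficient, $[30, 60]$ weak (L), $> 60$ strong (U); values are
not clipped before classification (only for display position, to $[0,1]$).
In *competition* the spec of "most accurately" is open; the package scores
accuracy as distance of the relative activation to the target band's
midpoint (45 for L, 80 for U), rewards the closer eligible participant and
both on exact ties. The success *flag* records whether a participant
reached the requested region — distinct from the reward, so two
well-calibrated partners can both succeed while only one is paid.

Exchange messages are single tab-separated lines (ISO-8601 timestamp, site,
block, block-local scan, `key=value` pairs; floats at 6 decimals) appended
to per-channel text files under a shared directory, the desk-scale stand-in
for a network drive. Readers poll with a byte cursor; partial trailing
lines wait for the next poll. If a partner's message has not arrived by the
feedback scan, social blocks are scored unsuccessful for both and flagged
`timeout` — a deliberate invention, since the protocol is silent on partner
dropout. Within `run_session()` messages are stamped with a simulated clock
(fixed epoch + scan index × TR) so that seeded sessions are reproducible
byte for byte.

## Simulated behavior and group comparison

`effort_policy()` maps a target region to an intended effort: Gaussian
around 0.45 (L) or 0.80 (U) — the band midpoints — with configurable SD
(default 0.08) and an optional attention-lapse probability producing
near-zero effort. These are simulation devices; no claim is made that they
model human motor control. The session summary compares the two sites'
per-block success indicators with a paired sign-flip permutation test,
which needs only exchangeability and replaces off-the-shelf
repeated-measures inference that would be meaningless for two synthetic
subjects.

`group_amplitude_summary()` averages response curves across a group
*before* taking the maximum; the mean of individual maxima is a different
(larger) summary whenever subjects peak at different lags, and the two must
not be conflated when reporting group amplitude ratios.

## Problem sizes and numerical choices

Tests and examples run on reduced geometries (16×16×10 to 24×24×12 voxel
volumes, 12–60 block schedules), chosen so the full suite exercises every
pathway — including complete two-site sessions — in well under a minute
while leaving the per-voxel arithmetic identical to full-size runs.
Correlation denominators are guarded so exactly constant voxels give `NaN`;
smoothing uses kernel truncation at $4\sigma$ with border renormalization
(constants are preserved exactly); connected components use an explicit
6-neighborhood BFS; schedule randomization, noise, drift phase and
behavioral draws each consume an isolated seeded RNG stream, so any
component can be replayed in isolation.

## Known limitations

* No motion, slice-timing, physiological-noise or distortion modeling; the
  simulator validates logic and calibration algebra, not artifact
  robustness.
* The undershoot carryover described above means consecutive active blocks
  are not perfectly independent trials, at the ~2% relative level.
* Human success rates from real experiments are not reproduction targets:
  success here is a function of the programmed effort policies.
* Transport is a local directory; network mounting, authentication and
  latency beyond an injected message drop are out of scope.
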