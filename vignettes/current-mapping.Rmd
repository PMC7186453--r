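---
title: "Mapping tDCS current-induced magnetic fields with dual-echo EPI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping tDCS current-induced magnetic fields with dual-echo EPI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcsmap)
```

## The measurement model

Transcranial direct current stimulation (tDCS) drives a weak constant
current (typically 1–2 mA) through scalp electrodes. By Ampère's law the
current induces a magnetic field; MRI phase is sensitive to the component
of that field along the scanner's main axis, `Bz`. At echo time `TE` the
accumulated phase of a voxel is

    phi = (gamma * Bz * TE) mod 2*pi

with `gamma` the proton gyromagnetic ratio (2.6752218744e8 rad/s/T, the
package default). The constant `gamma * TE2 * 1e-9` converts nanotesla to
radians: at `TE2 = 26` ms, 1 nT accrues 6.956e-3 rad (0.39°), and 3 nT
1.19° — small but measurable signals once many volumes are pooled in a
regression.

A dual-echo EPI (DE-EPI) acquisition reads two echoes per excitation. The
second echo (26 ms) is chosen for BOLD contrast, so its *magnitude* carries
the haemodynamic response while its *phase* carries the current-induced
field; the first echo (11 ms) accumulates fewer phase wraps and serves as
an anchor for unwrapping. Its magnitude is not used.

The applied current follows a block design: levels held constant over
blocks (1.5–3 min), in pseudo-random order, across several scans. A
per-voxel general linear model (GLM) of the unwrapped phase on the applied
current then yields a slope in rad/mA, converted to nT/mA by

    slope_nT = slope_rad / (gamma * TE2) * 1e9

and interpreted as the field induced per milliampere.

## Forward simulation (Biot–Savart)

`biotSavartBz()` computes `Bz` per mA from an explicit current path by
summing, for each straight segment, the exact finite-segment closed form

    B = mu0 * I / (4 * pi * d) * (cos(theta1) - cos(theta2))

along the azimuthal direction and retaining the z-component only. The
closed form was preferred over numerical quadrature because it is exact at
desk scale and removes any step-size tolerance question. Units are fixed
throughout: mm for geometry, mA for current, nT for field.

Voxels closer than `minDistance` to a segment are masked out; the line
current model diverges there. The default is half the smallest voxel
spacing. `phantomFixture()` builds the validation geometry — a long
straight insulated wire through the midplane of a water volume — and its
field shows the textbook bipolar pattern: `Bz(y) = -Bz(-y)` about the wire
plane, with a 1/d falloff that matches `analyticInfiniteWireBz()` (the
independent infinite-wire oracle) to better than 1% beyond two voxels once
the wire spans 20x the grid.

Volumetric current density from finite-element head models is out of scope
here; externally computed field maps can be supplied as NIfTI input
instead.

## The synthetic acquisition

`simulateSeries()` is the stand-in for the scanner. Per voxel, volume and
echo the noise-free complex signal is

    M * exp(i * (phi0_e + gamma*Bz*I(t)*1e-9*TE_e + drift*t + shift_scan))

with complex Gaussian noise added to the real and imaginary channels; the
stored phase is the wrapped argument in [-pi, pi) and the magnitude the
modulus (hence Rician-distributed). Key parameters:

* `te1 = 0.011` s, `te2 = 0.026` s, TR 4 s (phantom protocol) or 2 s
  (in-vivo protocol) — the acquisition timings being emulated.
* `baselineMagnitude = 100`, `complexNoiseSd = 2`: a complex SNR of 50,
  giving a per-sample phase noise of ~0.02 rad. This is the SNR regime in
  which the unwrapping robustness properties are stated.
* `backgroundFieldSd = 500` nT: the smooth static field inhomogeneity that
  gives each voxel its baseline phase. It is drawn as a random quadratic
  polynomial whose amplitude is calibrated over a fixed 100 mm reference
  box, not over the simulated grid. This matters: calibrating on the grid
  itself would make tiny grids unphysically steep (adjacent-voxel phase
  steps beyond pi at the long echo, which no unwrapping can resolve),
  whereas a fixed physical scale reproduces what a scanner sees — small
  fields of view contain proportionally less inhomogeneity, while a
  full-size grid still spans several wraps at TE2 (the reason the long
  echo needs a 4D unwrapper at all).
* `driftSlope` (rad/volume) and per-scan `levelShifts` (rad) emulate slow
  scanner drift and the abrupt constant offsets seen between scans.

An optional `BoldInjection` multiplies the *second-echo magnitude only* by
`1 + effectPerMA * (I ⊛ hrf)(t)` inside a region. The HRF is the canonical
double gamma (peak 6 s, undershoot 16 s, ratio 6) sampled at TR and
normalised to unit sum, so a sustained block converges to the block's
current level and regression betas read directly as change per mA.

Motion is deliberately not simulated: realignment is out of scope, and the
GLM accepts an external motion-parameter table (zeros by default, matching
a phantom analysis where realignment is skipped).

### The synthetic cohort

`cohortFixture()` emulates a small human study: each subject carries a
bilateral two-lobe field (opposite signs under a left "cathodal" and right
"anodal" patch, peak ~3 nT/mA — the upper end of the 1–3 nT range seen in
vivo at ~1 mA), with a multiplicative per-subject amplitude jitter
(SD 0.2), and a negative BOLD effect (default -0.15 per mA) injected under
the cathodal patch. The injected effect also carries a per-subject
multiplicative jitter (SD 0.2): inter-subject variability of the response
to stimulation is the salient empirical fact about tDCS, and a cohort of
identical responders would make group standard errors collapse to the
numerical noise floor, turning group-level recovery checks into tests of
floating-point bias rather than of the method. The waveform follows the
in-vivo protocol: levels 0/1/1.5/2 mA, 1.5-min blocks, two 12.5-min scans
at TR 2 s.

What the generator does **not** emulate: EPI distortion and k-space
artifacts, physiological noise, motion, coil phase offsets (the static
phase is purely field-driven, so phase scales exactly with TE), and any
real conductivity structure. Passing tests therefore demonstrate the
correctness of the estimation machinery under the stated signal model, not
robustness to every artifact of real data.

## Phase unwrapping (4D)

The long echo wraps several times across the volume, so unwrapping uses
three anchors in sequence (`unwrapDualEcho()`):

1. **Spatial:** volume 1 of echo 1 is unwrapped by quality-guided region
   growth. The quality score is the standard phase-derivative-variance
   criterion mapped to [0, 1] (1 / (1 + RMS of wrapped second
   differences)); growth starts at the highest-quality voxel and each new
   voxel is snapped to the 2*pi multiple nearest the mean of its already
   unwrapped 6-neighbours. Disconnected mask components each get their own
   seed.
2. **Echo bootstrap:** echo 2's first volume is unwrapped towards the
   TE-ratio prediction `phi1 * TE2/TE1`, valid when phase is dominated by
   static field inhomogeneity. One subtlety is resolved here: the echo-1
   unwrap is only defined up to a global 2*pi multiple, which the
   non-integer TE ratio turns into a constant *non*-2*pi offset of the
   prediction. That offset is identifiable — it is the circular mean of
   `wrap(phi2 - prediction)` — and is absorbed before the per-voxel
   snapping; a spatial-consistency region-growth pass follows.
3. **Temporal:** later volumes are unwrapped per voxel by 2*pi-jump
   counting, assuming the true phase moves less than pi between
   consecutive volumes (block transitions induce at most ~0.6 rad at the
   field strengths simulated here).

Voxels whose prediction residual still exceeds pi/2 are flagged; if more
than 20% of the mask is flagged the series is rejected as unusable (error
class `excessivePhaseWraps`). The 20% threshold is this package's explicit
choice of rejection rule. The global 2*pi ambiguity of the result is fixed
by placing the masked median of volume 1 inside (-pi, pi]; the GLM slope is
invariant to that convention.

Every unwrap output is congruent with its input modulo 2*pi to better than
1e-10 rad because only integer multiples of 2*pi are ever added. At
complex SNR 50 the *decision* error — the 2*pi-multiple part of the
deviation from the ideal unwrap, after removing per-volume global offsets
— is required to stay below 0.01 rad RMS; the raw deviation from noise-free
truth is of course bounded below by the ~0.02 rad phase noise floor, so the
property is stated about the decisions, which is what an unwrapper
controls.

## Field estimation (GLM)

`buildDesign()` assembles: intercept(s), linear trend(s), the applied
current (the predictor of interest, copied into the design exactly), six
motion parameters, the global signal (masked mean per volume, centred) and
level-shift step regressors from `detectLevelShifts()` (a boundary jump in
the across-mask mean phase beyond 3x the robust SD of within-scan jumps).

When the waveform spans several scans, the design uses per-scan intercepts
and per-scan centred trends. This is a correctness requirement, not a
flourish: the data are detrended per scan (`detrendLinear()`), and by the
Frisch–Waugh theorem the current slope is unbiased only if the design
spans the projection the detrending applied. A single global trend would
attenuate the slope by whatever per-scan trend component the pseudo-random
block order happens to contain. Step regressors that become redundant with
per-scan intercepts are dropped with a record; any other rank deficiency
is an error naming the offending columns.

`fitPhaseGlm()` is plain per-voxel OLS — no prewhitening or AR modelling,
a deliberate simplification (phase noise at these SNRs is close to white,
and the block design concentrates the signal at low frequency where OLS
remains unbiased regardless). Standard errors come from the residual
variance and `(X'X)^-1`. `fitMagnitudeGlm()` applies the same machinery to
the second-echo magnitude, reports percent signal change per mA
(`100 * slope / voxel-mean magnitude`), and controls family-wise error by
Bonferroni over mask voxels — chosen because it is exact, assumption-free
and conservative; nothing downstream depends on FWE power.

A noise-free simulated phantom session is recovered end to end (simulate →
unwrap → detrend → GLM) to better than 1e-6 nT/mA; with noise, the
estimator is unbiased to within Monte-Carlo resolution (mean bias < 2 SE
of the mean over 200 simulated sessions).

## Dephasing confounds on the BOLD signal

A field *gradient* across a voxel dephases spins and changes the
magnitude — a potential confound mimicking BOLD. Two closed-form bounds
are implemented (`confoundFraction()`), as functions of the intravoxel
phase spread `phi = gamma * |grad Bz| * TE2` where `|grad Bz|` is the
across-voxel field difference in nT per voxel step
(`gradientMagnitude()`, central differences, one-sided at edges):

* model 1: `1 - cos(phi/2)` — worst case, all spins at the two extremes;
* model 2: `1 - sin(phi/2)/(phi/2)` — linear spread across the voxel
  (removable singularity at 0 returns exactly 0).

Both vanish quadratically as `phi -> 0` (series `phi^2/8` and `phi^2/24`,
hence a small-angle ratio of 3), and model 1 dominates model 2 on
(0, 2*pi). `confoundTable()` forms `|fs_model / observed|` against observed
per-mA signal changes and reports 2-significant-figure ratios alongside
exact values. With a worst-case gradient of 1 nT per voxel at TE2 = 26 ms,
observed changes of -0.15 and -0.11 per mA give ratios of 4.0e-5/1.3e-5
and 5.5e-5/1.8e-5 — the dephasing confound is four orders of magnitude
below the observed effects. The reading of `phi` as the *across-voxel
field difference* is stated explicitly because it is the only reading
under which those ratios follow from the printed inputs.

## Validation statistics

* `spatialPearson()` — accuracy of a measured map against a simulation.
* `rangeRegression()` — OLS of measured on reference over progressively
  weaker field ranges (`|reference| <= bound`), demonstrating sensitivity
  down to the nT scale; rows with fewer than 3 voxels are flagged, not
  computed. Default bounds full/10/5/1 nT (configurable — the appropriate
  bounds depend on the field range the geometry produces).
* `pairedMeanFieldTest()` — paired two-sided t-test of per-subject mean
  fields, with an exhaustive sign-flip permutation option for small n.
  Note the exact two-sided permutation distribution at n = 7 has
  probability atoms of 1/64 (minimum attainable p = 2/128), so pointwise
  agreement with the t p-value at the 0.01 level is a property of the
  significance regime, not of arbitrary data.
* `iccAgreement()` — ICC(2,1): two-way random effects, absolute agreement,
  single measurement, with voxels as subjects and sessions as raters. The
  variant is fixed and named because the ICC family is ambiguous and the
  choice changes the number; it is validated against brute-force two-way
  ANOVA mean squares.
* `thresholdClusterMask()` — voxelwise p threshold then removal of
  26-connected components below a minimum size (26-neighbourhood being the
  fMRI convention).
* `diceCoefficient()` — overlap of binary maps; two empty maps are an
  error rather than a conventional value.
* `componentCurrentTest()` — dual-regression-style: stage 1 projects each
  volume onto a variance-normalised spatial map (a one-voxel map returns
  that voxel's timecourse, a binary region map the region mean); stage 2
  regresses the timecourse on the HRF-convolved current (convolution
  optional). The per-subject effect is reported as slope/intercept of the
  raw timecourse — exactly the fractional signal change per mA, directly
  comparable to a multiplicative injected effect. A z-scored variant is
  available but cannot recover a physical effect size (z-scoring removes
  the scale), which is why it is not the default. Group inference is a
  one-sample two-tailed t-test over subjects.

## Numerical choices and degenerate inputs

* Phase is stored in [-pi, pi); `wrapPhase()` maps pi to -pi. The
  symmetric interval keeps wrap arithmetic sign-free.
* Unwrapping adds only exact integer multiples of 2*pi, so congruence
  holds to ~1e-13 even after hundreds of volumes.
* All-zero or constant design columns are dropped with a record; a sham
  (all-zero) current column is dropped, and the phase GLM then refuses
  slope inference rather than returning zeros.
* Voxels with zero mean magnitude are excluded from percent scaling.
* Zero-variance maps are errors in correlation, ICC and timecourse
  extraction (no silent NaN propagation).
* Seeds: every stochastic routine takes an explicit seed and restores the
  caller's RNG state; identical seeds give bit-identical series.

## Problem sizes

The shipped tests and the acceptance script run the phantom sessions at
32 x 32 x 12 voxels (3.4 x 3.4 x 5 mm) with three 180-volume scans at
TR 4 s — the full protocol geometry. The Monte-Carlo estimator-bias check
uses 200 sessions of an 8 x 8 x 4 phantom with one 48-volume scan; the
cohort recovery check runs seven subjects at 20 x 20 x 8 voxels with the
full 750-volume waveform; the null-coverage check runs 40 five-subject
cohorts at 10 x 10 x 4 voxels with a 60-volume waveform. These sizes were
chosen so each property is measured with adequate Monte-Carlo resolution
while the whole suite stays interactive.

## Known limitations

* Only `Bz` is modelled and measured; reconstructing the full current
  density would require all three field components (or model fitting).
* The GLM is OLS without autocorrelation modelling; for real resting-state
  magnitude data the standard errors would be optimistic.
* Axis-aligned geometry only: oblique NIfTI affines are rejected
  explicitly rather than resampled.
* The unwrapping assumes phase scales with TE (field-inhomogeneity
  dominated); a large echo-specific (e.g. coil) phase would be flagged as
  excessive wraps rather than corrected.
* The simulator's noise is complex Gaussian (Rician magnitude); structured
  physiological noise is absent, so statistical power on synthetic cohorts
  is optimistic relative to real data.
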