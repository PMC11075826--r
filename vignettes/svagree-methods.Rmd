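---
title: "Methods: repeated-measures agreement for stroke-volume monitors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeated-measures agreement for stroke-volume monitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`svagree` implements the statistical machinery of a method-comparison
study of pulse-wave-analysis (PWA) versus suprasternal Doppler
ultrasound stroke volume under lower body negative pressure (LBNP) with
isometric handgrip (IHG), together with a synthetic beat-level cohort
generator that stands in for raw recordings, which are typically not
shareable. Everything downstream of raw signals is covered: derived
hemodynamic variables, trimmed 30-s aggregation with protocol-driven
exclusions, and mixed-model agreement statistics. The proprietary
three-element-Windkessel algorithm inside the PWA device is *not*
modelled mechanistically; the generator describes the device's output
statistically.

## The agreement models

All models are Gaussian linear mixed models estimated by REML with
`lme4`, with 95% Wald intervals and normal-approximation p-values
(the estimation method and interval type are the package's choices;
variance components are truncated at zero by the estimator itself).
Units are mL throughout; SVR is in mmHg·min·L⁻¹.

With $d_{ij}$ the PWA-minus-ultrasound difference of 30-s record $j$ in
subject $i$:

* **Bland–Altman**: $d_{ij} = \mu + b_i + e_{ij}$, $b_i \sim N(0,
  \sigma_b^2)$, $e_{ij} \sim N(0, \sigma_w^2)$. Bias $=\mu$; limits of
  agreement $=\pm 1.96\sqrt{\sigma_b^2+\sigma_w^2}$ (total variability);
  within-subject LOA $=\pm 1.96\,\sigma_w$ (residual SD only).
  Within-subject percentage error divides the within-subject LOA
  half-width by the mean of the paired-method averages; the denominator
  is the grand mean over analysis records by default, with a
  per-subject-then-grand alternative (`pe_denominator = "subject"`),
  since either reading of "mean of the averaged paired measurements" is
  defensible.
* **Sloped bias**: $d_{ij} = \mu + \beta\,\bar{y}_{ij} + b_i + e_{ij}$
  on the mean of methods $\bar{y}_{ij}$ (mL/mL). LOA about the fitted
  line reuse the same variance-component rule; the construction of
  sloped-line LOA is not standardized, and applying the
  $1.96\sqrt{\sigma_b^2+\sigma_w^2}$ half-width around the line is this
  package's convention.
* **SVR model**: the difference on $SVR_{US}$ (computed from the
  ultrasound stroke volume, the reference method, to limit data
  coupling), optionally with sex and a sex × SVR interaction;
  sex-specific slopes are reported as linear combinations with
  delta-method Wald intervals.
* **Time-proxy model**: because MAP, cardiac output and SVR are
  algebraically coupled, the SVR covariate is replaced by the ordinal
  30-s bin index (0–3) within handgrip periods — SVR rises almost
  linearly during a handgrip bout — with random intercepts for subject
  and for LBNP level nested in subject. The slope unit is mL per 30 s.
* **Precision**: per method, $1.96 \times$ the residual SD of a
  subject-random-intercept model on resting 30-s values at LBNP 0.

Degenerate inputs are refused rather than silently fitted: a single
subject (between-subject SD unidentifiable), a constant mean-of-methods
for the sloped model, a single sex for the interaction model. One
numerical special case is handled in closed form: intercept-only data
whose within-subject variation is numerically zero sit on the REML
boundary where the optimizer is unreliable, so the balanced one-way
closed form (subject-mean average, SD of subject means, zero residual)
is returned directly.

## The protocol and preprocessing rules

Each LBNP level (0, 20, 40, 60, 80 mmHg) lasts 6 minutes: a 2-minute
stabilization period, then two 2-minute periods alternating IHG and
rest, the opening phase alternating across levels from a
block-randomized start (block sizes 2 and 4). Handgrip is held at 40%
of the maximal voluntary contraction, itself the mean of three
attempts. Subjects stop at their decompensation level; only completed
levels are analysed.

Preprocessing applies, in order: removal of non-completed levels,
removal of every beat in the half-open 30-s window after each handgrip
release (release transients are extremely fast), and 30-s binning
aligned to period starts. Bin values are two-tailed trimmed means with
`ceiling(0.05 n)` values removed per tail — the ceiling rule keeps a 5%
trim active in bins of 25–50 beats; the rounding rule and the bin
alignment are package choices, as is beat membership by onset time in
half-open windows. Heart rate per bin is the trimmed mean of
instantaneous 60/RR (robust to edge beats). Bins with fewer than 5
beats are dropped. Stabilization bins are produced and flagged but
excluded from the agreement models by default
(`include_stabilization = TRUE` reverses this; whether such bins
belong in the analysis is genuinely open, and the default takes the
conservative reading that only the experimentally defined IHG/rest
states are of interest).

Derived variables: MAP is the time-weighted (trapezoidal) mean of the
pressure waveform over the beat; the velocity-time integral is the
trapezoidal integral of the non-negative aortic velocity; stroke volume
is VTI × LVOT area with a circular LVOT; cardiac output is SV·HR/1000;
SVR is MAP/CO with central venous pressure taken as constant zero (an
optional `cvp` argument supports sensitivity analyses). Body surface
area uses Du Bois (0.007184·h^0.725^·w^0.425^) by default — the
formula behind published BSA-indexed values is rarely stated, and Du
Bois is the cardiology workhorse — with Mosteller as an alternative.

## The synthetic cohort

### Latent trajectories

Per subject, stroke volume falls linearly with level
(`sv_baseline = 81` mL, `sv_drop_per_level = 12.23` mL), heart rate
rises mildly (`hr_baseline = 60` bpm, `+2` bpm/level), MAP is constant
at 85 mmHg except during handgrip, where it ramps linearly to
`+14.6` mmHg over the 2-minute bout. Latent SVR is emergent
(MAP/CO ≈ 17.5 at rest, ≈ 30 at the deepest levels, with ≈ +1–3 during
handgrip). Beats tile each period from its boundary with R-R intervals
from the heart-rate trajectory plus small jitter; no beat straddles a
period boundary, which keeps phase labels unambiguous.

The baseline of 81 mL is anchored to a resting BSA-indexed stroke
volume of 43.2 mL/m² at the cohort-mean Du Bois BSA (177 cm, 71 kg →
1.87 m²). Dropout draws each subject's stop level from
(1, 4, 9, 2)/16 over 20/40/60/80 mmHg, reproducing completion counts
of 16/15/11/2 per 16 subjects; non-completed levels are not generated
at all, because they never enter analysis. Sex follows a repeating
9-female/7-male pattern per 16 subjects.

### The discrepancy model and noise placement

The generator is the exact generative counterpart of the fitted
models. Per 30-s bin, both methods share the beat-to-beat physiological
stroke-volume variability (SD 10.13 mL), which cancels in their
difference but leaves each method's trimmed 30-s mean with a resting
residue of 3.7/1.96 mL — the source of the per-method precision. The
ultrasound value adds nothing else (it is the reference), so
$SVR_{US}$ computed from it is exactly the covariate the models use.
The PWA value adds

$$ d = \delta_0 + \beta_{SVR}\,(SVR_{US} - SVR_{ref}) + b_i + e $$

with $\delta_0 = 23.74$ mL at $SVR_{ref} = 17.49$, $\beta_{SVR} = 0.60$
(sex-specific 0.86/0.40 when enabled; their 9F/7M mixture equals 0.60),
$b_i \sim N(0, 14.46^2)$, and stress-dependent difference noise $e$
whose SD is 0.568 mL per unit of latent SVR elevation above rest.

Three placement decisions matter and were forced by internal
consistency of the reference quantities:

1. *No independent ultrasound-side 30-s noise by default.* Any such
   noise enters the difference (coefficient −1) and the SVR
   denominator simultaneously and would inflate the fitted SVR slope
   far beyond the generative value; attributing resting variability to
   the shared physiological component instead leaves the slope exact.
2. *The discrepancy responds to the measured SVR.* Regressing on a
   covariate the generator did not actually use would attenuate the
   slope; using the trimmed-mean-measured ultrasound value makes the
   within- and between-subject channels both carry slope
   $\beta_{SVR}$.
3. *Stress-dependent difference noise.* Resting per-method precisions
   of ±3.7 mL bound the resting difference noise near 2.7 mL, while
   the overall within-subject LOA of ±11.1 mL corresponds to a 5.66 mL
   residual SD — so the difference noise must grow with
   vasoconstriction. The generator scales it with the latent SVR
   elevation, which also makes residuals mildly heteroscedastic (a
   deliberate, documented departure from the homoscedastic model
   assumption; slope estimates remain unbiased, and interval coverage
   is checked by simulation in the test suite).

A small independent PWA-side 30-s noise (SD 0.92 mL) compensates the
discrepancy's partial cancellation of shared variability at rest so
that both methods show the same resting precision.

### Calibration of the defaults

The defaults are *defined* by recovery properties: fitting the full
pipeline to cohorts generated at the defaults must reproduce the
reference estimates (bias 27.0 mL, LOA ±30.1 mL, within-subject LOA
±11.1 mL, mean-of-methods slope −0.15 mL/mL, SVR slope 0.60, time
slope 0.58 mL/30 s, precisions ±3.7 mL). Six constants
(`sv_drop_per_level`, `map_ihg_boost`, `beat_noise_sd`,
`bin_noise_sd_pwa`, `sigma_within_slope`, `sigma_between`, `delta0`)
were solved by damped fixed-point iteration over pilot simulations
(`tools/calibrate_defaults.R`) and frozen. This is necessary because
several fitted quantities are composite: the mean-of-methods slope,
for example, combines the structural SVR–stroke-volume coupling with a
stable half-share of the PWA-side noise variance that leaks into the
mean of methods. The within-subject percentage error is *not* a
calibration target; it lands near the reference value as a consequence
of the others, which is a useful internal-consistency check.

### What the generator does and does not emulate

Emulated: the protocol's block structure and timing, per-level dropout,
stroke-volume decline, handgrip MAP/SVR ramps, an SVR-dependent
between-method discrepancy with between- and within-subject noise, and
measurement-scale beat/bin noise. Not emulated: baroreflex dynamics and
realistic LBNP tachycardia (heart rate rises only 2 bpm/level here —
with the steep stroke-volume decline the printed SVR excursion requires
falling cardiac output, which strong tachycardia would cancel; real
LBNP runs show substantially higher heart rates), respiratory
modulation and autocorrelated beat noise (beat noise is white, so the
trimmed-mean residue is slightly optimistic relative to correlated
physiological noise), device drift or recalibration events,
presyncope symptoms beyond a hard stop level, and any mechanistic
Windkessel behaviour of the PWA device. Passing parameter-recovery
tests therefore shows the *statistical pipeline* is correct and
internally consistent at realistic effect sizes — not that the
generator reproduces every feature of real recordings.

Waveform synthesis (`synthesize_beat_waveforms()`) exists to exercise
the MAP and VTI operations: a raised-cosine pressure pulse with exact
time-weighted mean and a half-sine systolic velocity whose integral
reproduces the beat's stroke volume, both within 0.5% at ≥ 100 Hz.

## Problem sizes and numerical choices

Parameter-recovery checks run 20 replicate cohorts of 200 subjects
(about 300 000 beats and 8 000 analysis bins each), a size at which
Monte-Carlo standard errors are a few per mille of the estimates while
a full run stays in the minutes range on one CPU; unit tests use
cohorts of 2–80 subjects. Seeds propagate from a single integer; a
cohort is bit-reproducible from its seed. Integrals are trapezoidal;
windows are half-open everywhere; p-values are two-sided with 0.05
used only for flagging, never filtering. Trimmed stroke volumes below
numerical floors (3 mL at the bin scale, 0.5 mL at the beat scale) are
clipped — reachable only in extreme noise tails at the deepest LBNP
level.

## Known limitations

* Limits of agreement are reported without confidence intervals (the
  CI construction for variance-derived LOA under repeated measures is
  unsettled; bootstrap CIs are out of scope).
* The Wald/normal inference ignores small-sample t corrections; at the
  package's recovery scale this is immaterial, but at 16 subjects
  intervals are mildly optimistic.
* The sloped-bias LOA convention (constant half-width about the fitted
  line) is one of several in the literature.
* Real exported data are accepted through the same beats.csv schema as
  the generator writes, but R-peak detection, artifact screening and
  signal quality control are upstream of this package.
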