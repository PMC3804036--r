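---
title: "Assessing pulse depth from tonometric recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing pulse depth from tonometric recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsedepth)
```

## The problem

Pulse palpation at the radial artery distinguishes *floating* (shallow)
from *sunken* (deep) pulse qualities by how the pulse strength varies
with applied force. Devices quantify this by pressing a pressure sensor
into the tissue and tracking the pulse amplitude. Two families of depth
measures exist:

* **contact-pressure based**: the amplitude is plotted against contact
  pressure (the P–H curve) and summarised either by the pressure of
  maximal amplitude (OCP, normalised to `CFS_ocp`) or by the
  deep-vs-shallow amplitude balance (`CFS_pad`);
* **displacement based**: under a constant-velocity advance (CETM) the
  sensor's travel is known at every instant (`SD = v · t`), and the
  **pulse depth index (PDI)** is the displacement from skin contact to
  the point of maximal amplitude, in millimetres.

The two families are not interchangeable because contact pressure is a
nonlinear function of displacement: elastic (linear) at small
indentation, approximately quadratic beyond, and diverging as the
artery approaches occlusion. This package implements all three indices,
the processing pipeline that extracts them from raw recordings, the
CP–SD nonlinearity analysis, and the cohort statistics used to compare
indices — plus a synthetic tonometry generator that provides ground
truth for every stage.

## The synthetic tonometry model

`simulation_config()` collects the generator's parameters; defaults are
chosen to mimic a radial CETM acquisition.

* **Acquisition**: 200 Hz sampling; actuator velocity 0.09 mm/s;
  80 s duration with skin contact at 3 s, so the sensor travels about
  6.9 mm beyond contact — past the amplitude peak but safely below the
  8 mm occlusion depth.
* **Tissue response**: `CP(sd) = a·sd + b·sd²` with defaults
  `a = 5 mmHg/mm`, `b = 8 mmHg/mm²`. At the default optimal depth of
  3.8 mm this puts the optimal contact pressure near 134 mmHg, a
  typical mid-range value for radial tonometry. Beyond 90% of the
  occlusion depth a hyperbolic term `k·(sd−s₀)²/(D−sd)` is added; it
  vanishes with zero slope at the blend point, so the response is C¹,
  strictly increasing, and diverges at occlusion. The blend point at
  `0.9·D` keeps the entire default analysis window inside the pure
  linear-plus-quadratic regime.
* **Amplitude envelope**: a Gaussian bell
  `A(sd) = A₀·exp(−(sd−d_opt)²/(2w²))`, default peak 25 mmHg and width
  1.5 mm. The only property the science requires is a unique interior
  maximum; the Gaussian gives an analytic argmax (the ground-truth PDI)
  and one interpretable width parameter.
* **Beat waveform**: a truncated Fourier series `Σ sin(2πkφ)/k`
  (3 harmonics), which has the sharp systolic upstroke and gradual
  decay of an arterial pulse. Because a smooth periodic waveform has no
  unambiguous "start", the ground-truth onset is defined by the same
  fiducial the field uses on real pulses: the intersecting-tangent foot
  of the continuous waveform. The waveform is re-anchored so that
  phase 0 is that foot, with value 0 there and 1 at the systolic peak;
  the diastolic minimum then sits slightly below zero, exactly as the
  tangent construction implies. With this convention the generator's
  envelope parameterises the *measured* (peak-minus-foot) amplitude,
  and beat k of a recording truly starts at `contact + k·60/HR`.
* **Noise and wander**: additive white sensor noise (default SD
  1 mmHg) and respiration wander (default 3 mmHg at 0.25 Hz). Real
  device noise levels are rarely published; these defaults are
  plausible placeholders and fully configurable. Wander is modelled as
  a modulation of the contact coupling — its amplitude scales with
  `min(1, CP/20)` — because breathing cannot modulate a force that is
  not yet applied; a discontinuous wander onset at skin touch would be
  an artefact.
* **Stepwise protocol**: `simulate_stepwise()` holds contact pressure
  at five steps (defaults 40/70/110/140/180 mmHg, 5 s each); the
  displacement at each step comes from numerically inverting `CP(sd)`
  by bisection to 10⁻⁶ mm, and the beat train is scaled by the
  envelope at that displacement.
* **Cohorts**: `simulate_cohort()` draws per-subject optimal depths
  around per-location means (defaults 3.76 / 3.60 / 5.01 mm for the
  Chon / Gwan / Cheok palpation sites, the pattern reported for adult
  cohorts), between-subject SD 0.6 mm and repeat-to-repeat jitter
  0.2 mm. The jitter was set so that test–retest CVs land in the
  6–13% range typical of repeated tonometric depth measures. Location
  stiffness defaults order the CP–SD curves (Gwan stiffest, Cheok
  softest) and their effective power-law exponents (Gwan < 2, Cheok
  slightly above, Chon highest). Everything is reproducible from one
  master seed; per-recording seeds are drawn from the master stream.

## Signal processing choices

* **Filtering**: all filters are zero-phase (forward–backward
  Butterworth) so that onset timing carries no group delay. The beat
  detection band is 0.5–20 Hz (fundamental plus ~10 harmonics at
  rest); the trend cut-off is 0.3 Hz. Signals are extended by odd
  reflection before filtering; the reflection is anchored on a short
  local linear fit rather than the single edge sample, since anchoring
  on one noisy sample would inject a DC step of twice that sample's
  noise into the filter startup.
* **Trend/pulsatile decomposition** (`remove_baseline()`): first pass
  uses the 0.3 Hz low-pass trend; after beats are found, the trend is
  re-anchored as a natural cubic spline through the beat feet, which
  pins the pulsatile feet at zero and makes the trend the per-beat
  contact-pressure estimate. `trend + pulsatile` reconstructs the
  denoised signal exactly. In CETM recordings the pressure ramp is
  deliberately part of the trend.
* **Beat detection** (`detect_onsets()`): candidate peaks from local
  maxima above an adaptive threshold (a fraction of the rolling 90th
  percentile of |signal| over ±2 s, with an absolute floor of five
  times the noise scale estimated from the quietest 1 s segments).
  Harmonic ripple can produce secondary bumps on the decay; peaks
  separated by a valley that stays above half their height are merged,
  since a true systolic peak is preceded by a foot near baseline.
  Onsets are refined by the intersecting tangent: the tangent at the
  maximum upslope (5-sample centred difference, 25 ms at 200 Hz)
  intersected with the horizontal through the preceding minimum,
  clamped to [preceding minimum, upslope point]. Inter-beat intervals
  outside 0.3–2 s (30–200 bpm) are dropped.
* **Amplitudes** (`measure_amplitudes()`): peak-to-foot, the foot
  being the pulsatile value at the onset sample. Peak search windows
  are bounded by 1.5 median inter-beat intervals so a missed neighbour
  cannot extend a window into foreign territory, and an incomplete
  final cycle is dropped.
* **Contact detection** (`detect_contact_point()`): the trend must
  exceed `pre-contact mean + 5 SD + 2 mmHg` for 0.5 s (robust coarse
  anchor), then the estimate walks back on a 1 Hz zero-phase trend to
  the last sample within a small margin of baseline. Timing accuracy
  is intrinsically limited by the slow initial pressure growth
  (≈0.45 mmHg/s at the default stiffness); residual errors of a
  second translate to <0.1 mm of displacement, i.e. they are
  negligible at the scale of the depth index. The refinement is exact
  to within ~0.1 s on noiseless input and bounded within ~2 s at the
  default noise.
* **Envelope** (`build_envelope()`): one `(sd, cp, H)` triple per beat
  with `sd = v · onset time` (actuator origin) and `cp` the trend at
  the onset instant, so the pair refers to the same moment; stepwise
  recordings contribute one point per step (median amplitude at the
  nominal step pressure, the first 0.5 s of each step trimmed as a
  transition).
* **Indices**: CETM envelopes are smoothed by a 5-beat moving median
  followed by a 5-beat moving average before the argmax is read — one
  aberrant beat must not decide the maximum; ties break toward the
  shallowest displacement/pressure. Stepwise OCP interpolates the five
  P–H points with a natural cubic spline and maximises on a fine grid.
  An argmax on the envelope boundary is returned with a flag rather
  than silently trusted.

## Cohort statistics

* **Repeatability CV**: per subject-location,
  `100·sd(repeats)/mean(repeats)` with the sample (n−1) SD; the
  per-location figure is the mean over subjects by default (a pooled
  root-mean-square mode is provided, since either aggregation is
  defensible for two repeats).
* **ANOVA**: classical one-way fixed effects via `lm()`; if all values
  are identical, F is defined as 0 with p = 1.
* **Duncan's multiple range test**: ordered means; a stretch of p means
  is heterogeneous when its range exceeds
  `qtukey(1 − α_p, p, df) · sqrt(MS_within / n_h)` with protection
  level `α_p = 1 − (1−α)^(p−1)` and harmonic-mean group size `n_h`;
  non-significant stretches merge into homogeneous letter groups. With
  two groups this reduces to a single studentized-range test, which the
  test suite uses as a closed-form oracle.
* **R²**: squared Pearson correlation of the linear fit.

The ANOVA/Duncan comparison of an index across locations uses
subject-level means over the repeats, so the repeated measures do not
masquerade as independent subjects.

## CP–SD characterisation

`cpsd_fit()` fits `CP = c₀ + c₁·SD + c₂·SD²` by least squares and
reports R², plus a power-law exponent as the OLS slope of
`log CP` on `log SD` inside an explicit window (default: the upper half
of the displacement range of the supplied data). The window must
exclude the origin and should exclude the near-occlusion divergence;
reading the exponent from an explicit log–log regression, rather than
from visual comparison of quadratic fits, makes the estimate
reproducible and scale-invariant. On the default tissue model the
exponent lies between 1 and 2 and grows with the quadratic share of
the stiffness.

## What the tests do and do not show

The simulator provides what clinical recordings cannot: exact ground
truth for contact time, beat onsets, the amplitude envelope and the
depth. The test suite (and `scripts/acceptance.R`) verify on that basis
that the pipeline recovers a uniformly drawn optimal depth within
±0.3 mm in ≥90% of seeded runs at the default noise, that onset timing
is within 10 ms median (sub-millisecond noiseless), that stepwise and
CETM protocol readings of OCP agree on the batch mean within 15 mmHg,
and that the simulated three-location cohort design separates the deep
location (and only it) by ANOVA + Duncan in ≥95% of cohorts.
Problem sizes were chosen to keep the whole suite around half a minute:
50-recording recovery batches, 20 protocol pairs, 100 cohorts at the
parameter level and one full-pipeline cohort.

Passing these tests shows the pipeline is a faithful estimator *of the
model it simulates*. Real recordings add phenomena the generator does
not emulate: heart-rate and amplitude variability, motion artefacts,
multi-channel sensor geometry (the package analyses one effective
channel), reflected-wave morphology changes with pressure, and
tissue viscoelasticity (hysteresis between advance and dwell). Those
require validation against measured data and are out of scope here.

## Known limitations

* PDI requires the CETM protocol; stepwise recordings return the
  CP-based indices with PDI marked not-applicable.
* Envelope resolution along SD is one beat spacing
  (`v·60/HR ≈ 0.07 mm` at defaults); noise moves the smoothed argmax
  by up to a few tenths of a millimetre, which bounds the achievable
  PDI repeatability.
* Contact-time estimation degrades gracefully but inevitably as the
  initial stiffness approaches zero (nothing to detect); an explicit
  `contact_time_s` override is available.
* Single-run OCP readings on noisy continuous envelopes carry
  irreducible argmax jitter (tens of mmHg at steep parts of the CP
  ramp); batch means are the meaningful comparison unit.
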