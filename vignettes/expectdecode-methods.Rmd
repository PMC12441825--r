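---
title: "Models and methods behind expectdecode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind expectdecode}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expectdecode)
```

This vignette documents the statistical models the package implements, the
assumptions they make, the tunable parameters and their defaults, what the
synthetic generators do and do not emulate, and the numerical conventions
adopted where the design was genuinely open.

## The experimental design

A trial presents a visual cue (an oriented line), then after a uniform
250–1500 ms delay a motor cue prompting a button press, then a target whose
orientation the participant reproduces. Two probabilistic manipulations are
crossed:

* **visual expectancy** — with probability 0.75 the cue's orientation equals
  the target's; otherwise the target differs from the cue by an orientation
  distance drawn uniformly from (30°, 90°];
* **motor expectancy** — with probability 0.75 the target appears immediately
  on button release; otherwise after an extra delay drawn uniformly from one
  third of the cue-delay width, i.e. (0, 416.67] ms for the default range.

`generate_schedule()` balances cell counts *exactly at the experiment level*:
720 trials split into exactly 405/135/135/45. Per-block exact balancing is
arithmetically impossible (72 × 9/16 = 40.5), so condition labels are
pseudo-randomly interleaved across blocks instead; this reproduces the
whole-experiment arithmetic (720/16 = 45) deterministically. Cue–target
equality on expected trials is exact (no jitter), and the motor-unexpected
extra delay excludes zero so "unexpected" is always a strict delay.

Because expected cells are three times larger than unexpected ones, and
motor-unexpected trials are systematically longer, `match_trials()` equates
the four cells at the smallest cell's size by discarding, within each
over-represented cell, the trials with the *longest* cue-to-motor delays
(ties broken by trial index, original order preserved, idempotent). Note what
this does and does not achieve: counts are equated exactly (45 per cell for
the default design), and the retained expected trials are biased toward short
delays, but the retained delay *distributions* of trimmed and untrimmed cells
are not equal — the smallest cell keeps its full uniform delay distribution
while trimmed cells keep only the short end. Analyses that are sensitive to
delay per se should treat delay as a covariate rather than rely on the
subsampling.

## The inverted encoding model

The forward model is `B = WC + E`: `B` (sensors × presentations) is the
epoched EEG at one timepoint, `C` (5 × presentations) holds the responses of
five hypothetical orientation channels, `W` (sensors × 5) their sensor
projections. Channels prefer 0°, 36°, 72°, 108°, 144° (the 180° endpoint is
the alias of 0°) and have tuning `max(0, cos(π(θ−φ)/90))⁴` — a half-wave
rectified cosine on the doubled-angle circle, raised to the fourth power,
zero at orientation distances of 45° and beyond.

Estimation, per cross-validation fold and per timepoint independently:

1. `B` and `C` are centred across presentations (training-fold means; the
   held-out fold is centred with the *training* means so the test transform
   never uses test statistics);
2. `wᵢ = B cᵢᵀ/(cᵢ cᵢᵀ)` — one-regressor least squares per channel, exactly
   as the model is written, not a joint multichannel regression;
3. residuals `εᵢ = B − wᵢcᵢ` give `Σ̂ᵢ = εᵢεᵢᵀ/(n−1)`, shrunk toward the
   scaled identity `νI` (ν = mean diagonal) with the analytic Ledoit–Wolf
   intensity λ ∈ [0, 1]; shrinkage guarantees an invertible, well-conditioned
   covariance even when sensors outnumber training presentations;
4. `vᵢ = Σ̃ᵢ⁻¹wᵢ/(wᵢᵀΣ̃ᵢ⁻¹wᵢ)` — the unit-gain (`vᵢᵀwᵢ = 1`) filter with
   minimal residual variance, which suppresses the strong correlations
   between neighbouring sensors;
5. `C_test = Vᵀ B_test`, and each reconstructed response vector is decoded
   with the doubled-angle population vector `z = Σₖ cₖ e^{2iφₖ}`,
   `θ̂ = arg(z)/2` mapped to [0, 180).

Degenerate cases are defined, not fatal: zero training residuals (noiseless
data) collapse the noise model to the identity covariance; a response vector
whose phasors cancel (|z| ≤ 10⁻¹² × Σ|cₖ|) yields an *undefined* decode
(`NA`), which accuracy computations exclude and count.

Accuracy is `r̂ = Re[(1/n) Σⱼ exp(2i(θ̂ⱼ−θⱼ))]`. The angular differences are
doubled before exponentiation, consistent with the doubled-angle mapping used
in the decoder; `decoding_accuracy(..., double_angle = FALSE)` selects the
raw-angle variant for comparison.

### Known property: the decoder is biased at the single-trial level

The rectified-cosine-to-the-fourth tuning contains Fourier harmonics beyond
the first; with five equally spaced channels the 4th and 6th harmonics alias
onto the 1st, so the population-vector decode of even the *exact* channel
responses deviates from the true orientation by up to ±5.3°, periodically in
θ. This is a property of the basis/decoder pair, not of noise: per-trial
decodes do not converge to the true orientation as SNR grows. The bias is
odd-symmetric and averages out over uniformly distributed orientations, and
it costs little in the accuracy metric (cos of a doubled 3° error is ≈ 0.995),
which is why closed-loop tests assert peak accuracy above 0.9 rather than
degree-level per-trial recovery. For the same reason, rotating all stimulus
orientations by Δ shifts decodes by exactly Δ only when Δ is a multiple of
the 36° channel spacing (and, because the shrinkage target νI lives in sensor
space, only under an isometric sensor embedding); the equivariance test uses
that exact case.

Training pools all trials of the matched (balanced) schedule across cells;
accuracy is reported per cell. Whether the original analysis trained on all
or only expected trials is not documented; pooling uses all information and
keeps the training set identical across the conditions being compared.

## Behavioural mixture model

Errors `e = wrap(response − target) ∈ (−90°, 90°]` are doubled onto the full
circle. The reported dispersion is the circular standard deviation
`σ = ½√(−2 ln R₂)·180/π` with `R₂` the mean resultant of the doubled errors;
above 60° the estimate is unstable (near-uniform data) and a
`large_dispersion` flag is set.

The mixture `(1−g)·vM(2e; 0, κ) + g/(2π)` is fitted by L-BFGS-B from a
deterministic 5 × 5 grid of starts (κ ∈ {0.5, 2, 8, 32, 128},
g ∈ {0.05, …, 0.95}), κ bounded to [0, 200] — the range over which the
exponentially scaled Bessel ratio is numerically stable; hitting the bound
sets a flag rather than failing. Ties are resolved by highest log-likelihood,
then lowest κ. κ is reported in doubled-angle units throughout. One genuine
identifiability ridge exists: at κ = 0 the von Mises component is itself
uniform and any g fits identically; that ridge is reported in its pure-guess
representation (κ = 0, g = 1). The fit requires at least 20 trials
(configurable floor).

## ANOVA, effect sizes, Bayes factors

`rm_anova_2x2()` computes the full within-subject decomposition; each effect
is tested against its own effect-by-subject interaction, `df = (1, n−1)`, and
`η²ₚ = F·df₁/(F·df₁+df₂)`. For 2-level factors this F equals the squared
paired t on the per-subject contrast scores — the identity the vectorised
time-series engine exploits (and a test verifies).

Bayes factors use the JZS construction: a Cauchy prior with scale √2/2 on the
standardised effect of the paired contrast, integrated numerically
(`integrate`, relative tolerance 10⁻⁹). The BF attached to an ANOVA effect is
the paired JZS test of that effect's marginal means — the source cited for
the Bayes factors does not pin down an ANOVA-specific construction, so the
package uses the transparent paired form and documents it. Zero-variance
differences return `Inf` (non-zero mean) or `NaN` (identically zero), since
the t statistic is undefined there.

## Cluster-mass permutation statistics

For a subjects × 4 × timepoints panel, per-timepoint 2×2 ANOVAs give F time
courses; clusters are maximal runs of temporally adjacent points with
`p < cluster_alpha` (strict, default .05; adjacency = consecutive samples
only); a cluster's mass is its summed F. Under the omnibus null the four cell
labels are exchangeable within subject, so each permutation draws one random
relabelling per subject and applies it across *all* timepoints — preserving
temporal autocorrelation — and contributes its largest cluster mass (0 if
none) to the null. Corrected p-values use the `(1+k)/(1+N)` estimator so they
are never zero; a cluster is significant when its mass exceeds the null's
95th percentile. The interaction is permuted with the same omnibus shuffle;
restricted interaction-specific schemes are out of scope. The same machinery,
with per-subject sign flips, tests accuracy time courses against chance.

The permutation engine is exact but vectorised: the 24 label permutations
induce sign patterns on each effect's contrast, so a permutation stream
reduces to one (n_perm × 4) × (4 × timepoints) matrix product per subject and
effect. A 20-subject, 180-timepoint, 1000-permutation run takes a fraction of
a second, which is what makes the 500-experiment familywise-error simulation
routine.

## Time-resolved LDA

Per timepoint, features are all sensor amplitudes; the classifier is
`w = Σ̃⁻¹(μ₁−μ₀)` with the pooled within-class covariance shrunk analytically
(same estimator as the IEM noise model) and the threshold at the midpoint of
the projected class means. Because the design is 75/25 imbalanced by
construction, the majority class is subsampled to the minority count — a
fresh draw per repeat — before stratified k-fold cross-validation; without
this, a degenerate classifier scores 75% and "chance" is undefined. Features
at a single timepoint (no window stacking) keep the classifier's temporal
resolution at one sample.

## Synthetic generators: what they emulate, and what they do not

All generators are pure functions of their arguments and a seed.

* **EEG** (`simulate_eeg`): data = α·W·c(θ)·profile(t) + spatially correlated
  Gaussian noise. The ground-truth `W` is drawn once per dataset from
  standard normals smoothed over neighbouring sensors (any full-rank `W`
  suffices for recovery testing); the temporal profile is a raised cosine
  over the 50–300 ms signal window; noise covariance decays exponentially
  with sensor-index distance (`exp(−d/λ)`, λ = 2), emulating the high
  neighbour correlations that motivate the covariance-aware filters. `snr`
  is the RMS ratio of signal (inside its window) to noise; no published
  value exists for it, so it is a calibration dial for tests, with snr = 0
  the exact null. Not emulated: 1/f spectra, biophysical forward models,
  eye-movement artifacts.
* **Behaviour** (`simulate_behavior`): the exact mixture the fitter assumes,
  per-cell κ and g (defaults κ = 8, g = 0.25 — mid-range values for
  orientation reproduction). Parameter-recovery tests are therefore
  well-specified-model tests; they bound estimator error, not model
  misspecification.
* **Pupil** (`simulate_pupil`): smoothed-random-walk baseline drift,
  a gamma-form impulse response (peak 930 ms, shape 10.1) scaled per
  condition cell, white measurement noise, disjoint missing-sample blink
  segments and sporadic large outliers. Defaults give motor-expected cells
  the larger dilation (0.5 vs 0.3 z). Real pupil data add gaze-dependent
  foreshortening and correlated measurement noise that this generator does
  not model.

Passing closed-loop tests shows the estimators invert their own generative
assumptions correctly; it does not certify performance on real recordings.

## Preprocessing conventions

The pupil pipeline applies, in this order and no other: blink buffering
(±100 ms), MAD outlier rejection (|x−median|/MAD > 2.5, MAD with the usual
1.4826 normal-consistency constant), linear interpolation, zero-phase
first-order Butterworth filtering, z-scoring of the continuous trace,
epoching to [−500, 1500] ms, down-sampling to 125 Hz (exactly 250 samples).
The executed order is recorded in the result and asserted by a test. Epochs
extending beyond the trace, or entirely missing before interpolation, are
excluded and logged rather than raising errors. The historically reported
passband (15.6–500 Hz) lies far above pupil dynamics (< 4 Hz) and would
remove nearly all signal of interest; it remains the default for fidelity but
triggers a loud warning, and the package's own validation runs use a 4 Hz
low-pass profile. No baseline correction is applied to either EEG or pupil
epochs by default, as none is part of the documented pipeline.

EEG epochs are band-limited at 0.1–45 Hz (4th-order zero-phase Butterworth),
resampled to 256 Hz and cut to [−200, +500] ms around the target (or motor
cue). At 256 Hz that window yields `round(0.7·256) = 179` samples; timepoint
counts are always derived from rate × window rather than hard-coded, since no
consistent published sample count exists for this combination. Artifact ICA
and bad-channel interpolation are upstream, ingest-time responsibilities; the
pipeline consumes already-clean continuous data.

## Problem sizes used in validation

The package's own validation uses desk-scale simulations chosen to keep the
whole suite in the minutes range while leaving Monte-Carlo error well inside
the asserted tolerances: chance-level LDA calibration averages 6–20
signal-free datasets of 720 trials; familywise-error calibration uses 500
null experiments of 20 subjects × 180 timepoints with 1000 permutations each
(the binomial standard error at 0.05 is then ±0.01); mixture recovery uses 50
datasets of 540 trials; closed-loop decoding uses 160-trial, 16-sensor
datasets. All sizes are set in the tests and the acceptance script, not in
the package code.

## Known limitations

* Single-trial orientation decodes carry the ±5.3° basis-aliasing bias
  described above; condition contrasts of the accuracy metric are unaffected.
* The confound-matching subsample equates counts, not delay distributions.
* The JZS Bayes factor is the paired-contrast form, not a model-comparison
  ANOVA BF; values are therefore comparable within this package, not across
  arbitrary BF implementations.
* The cluster test controls the familywise rate per effect under the omnibus
  exchange; interaction inferences inherit the omnibus permutation scheme.
* Optional ingest of real recordings covers plain-text formats (CSV, EyeLink
  ASC subset); binary vendor formats are out of scope.
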