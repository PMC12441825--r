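# expectdecode

Tools for building and validating the analysis chain of cross-domain
probabilistic-cueing experiments: designs in which a visual cue predicts a
target's orientation and a motor cue predicts its onset timing, each with 75%
validity, and the question is whether fulfilled expectations sharpen or dampen
the neural representation of the stimulus. The package implements the full
pipeline — trial-schedule generation, inverted encoding decoding of
orientation from multichannel EEG epochs, mixture modelling of
continuous-reproduction errors, cluster-mass permutation statistics for time
series, time-resolved expectancy classification, and pupillometry
preprocessing — together with synthetic generators that produce EEG,
behavioural and pupil data with known ground truth, so every estimator can be
validated closed-loop.

It is aimed at cognitive-neuroscience researchers who run probabilistic-cueing
/ expectation-suppression EEG studies and want a tested, deterministic
implementation of these analyses in R.

## What is implemented

**Design.** A counterbalanced 2×2 schedule over visual expectancy (cue matches
the target vs. differs by >30°) and motor expectancy (immediate target onset
vs. an extra delay drawn uniformly from one third of the 250–1500 ms cue-delay
range). With 10 blocks of 72 trials the four cells occupy exactly
56.25/18.75/18.75/6.25% of trials; confound-matching subsampling
(`match_trials`) equates the cells at 45 trials each by discarding the
longest-delay trials from over-represented cells.

**Inverted encoding model.** A forward model *B = WC + E* maps five
hypothetical orientation channels (half-wave-rectified cosines raised to the
fourth power, preferences every 36°) to sensors. Per channel *i*, weights are
estimated by least squares,

  wᵢ = B cᵢᵀ / (cᵢ cᵢᵀ),

residual covariances Σ̂ᵢ = εᵢεᵢᵀ/(n−1) are regularised by analytic
(Ledoit–Wolf-type) shrinkage toward the scaled identity, and unit-gain
minimum-noise spatial filters

  vᵢ = Σ̃ᵢ⁻¹wᵢ / (wᵢᵀΣ̃ᵢ⁻¹wᵢ)   (so vᵢᵀwᵢ = 1)

reconstruct channel responses on held-out folds, C_test = Vᵀ B_test.
Orientation is decoded with the doubled-angle population vector
z = Σₖ cₖ e^{2iφₖ}, θ̂ = arg(z)/2, and accuracy is the projected mean
resultant r̂ = Re[(1/n) Σ e^{2i(θ̂−θ)}] per timepoint and condition.

**Behaviour.** Reproduction errors live on the doubled-angle circle; the
mixture density (1−g)·vonMises(2e; 0, κ) + g/(2π) separates precision (κ)
from guessing (g), fitted by bounded multi-start maximum likelihood.
Condition effects are tested with 2×2 within-subject ANOVAs (partial
η² = F·df₁/(F·df₁+df₂)) and JZS Bayes factors (Cauchy prior, r = √2/2).

**Time series.** Per-timepoint 2×2 repeated-measures ANOVAs with cluster-mass
permutation correction (clusters = runs of p < .05 points, mass = summed F,
null = per-permutation maximum mass under within-subject shuffling of the four
cell labels), per-timepoint Bayes factors, and a one-sample sign-flip variant
for testing classification accuracy against chance.

**LDA.** Time-resolved shrinkage LDA classifies trials by expectancy from all
sensor amplitudes at each timepoint, with repeated majority-class subsampling
so that the 75/25 design imbalance cannot masquerade as decodable signal.

**Preprocessing.** Pupil traces: blink removal with a 100 ms buffer, MAD > 2.5
outlier rejection, linear interpolation, zero-phase first-order Butterworth
filtering, z-scoring, epoching to [−500, 1500] ms and down-sampling to 125 Hz
(250 samples per epoch). EEG: 0.1–45 Hz zero-phase band-limiting, resampling
to 256 Hz, event-locked epoching, occipital-parietal ROI averaging.

## Worked example

```r
library(expectdecode)

sched <- generate_schedule(n_blocks = 10, trials_per_block = 72, seed = 42)
sched
#> Trial schedule: 720 trials in 10 block(s)
#>   cells: VEME=405, VEMU=135, VUME=135, VUMU=45
#>   seed: 42

matched <- match_trials(sched)          # 45 trials in every cell
table(cell_labels(matched))
#> VEME VEMU VUME VUMU
#>   45   45   45   45

# synthetic orientation-tuned epochs and closed-loop decoding
ds  <- simulate_eeg(matched, tuning_config(n_sensors = 32, snr = 2), seed = 42)
dec <- crossvalidated_decode(ds, k = 10, seed = 42)
dec
#> IEM decode result: 180 trials x 179 timepoints (10-fold CV)
#>   peak accuracy 0.987 at timepoint 100; undefined decodes: 0

# synthetic reproduction behaviour and mixture modelling
resp <- simulate_behavior(matched, behavior_truth(kappa_per_cell = 8,
                                                  guess_rate_per_cell = 0.25),
                          seed = 42)
err <- response_error(resp, matched$target_orientation_deg)
err
#> Error sample: n = 180, circular SD = 23.23 deg
fit_mixture(err)
#> Mixture fit: kappa = 11.800, guess rate = 0.273, logLik = -181.94 (n = 180)
```

The decode peaks at timepoint 100 (≈ 187 ms post-target), inside the 50–300 ms
window where the generator injects orientation-tuned signal; accuracy 0.987
means the decoded orientations are nearly perfectly aligned with the presented
ones on the doubled-angle circle. The mixture fit recovers the generating
parameters (κ = 8, g = 0.25) to within the sampling error expected at 180
trials.

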