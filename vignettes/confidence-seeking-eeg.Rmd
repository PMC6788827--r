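---
title: "Decoding confidence-driven information seeking from synthetic EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding confidence-driven information seeking from synthetic EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seekEEG)
```

## The scientific problem

When a perceptual decision is made with low confidence, a rational agent
should be more willing to pay a small cost to sample additional evidence
before committing. seekEEG implements, end to end, the analysis chain used
to ask whether the *neural* representation of decision confidence is the
signal that drives such information-seeking choices: if a multivariate
classifier trained to discriminate high- from low-confidence EEG epochs
also predicts, on separate trials, whether the observer chose to see the
stimulus again, the two behaviors share a neural code.

The package has two halves:

1. a **forward simulator** of the whole study — a color-mean
   discrimination task with free/no-choice evidence sampling, an
   evidence-based observer, and EEG epochs containing confidence-coupled
   P3 (stimulus-locked) and Pe (response-locked error positivity)
   components in spatially correlated noise; and
2. the **analysis chain** — preprocessing, univariate ERP statistics with
   1-D cluster-based permutation tests, and the sliding-window
   linear-derivation logistic decoding machinery with temporal
   generalization, across-condition transfer, shuffled-label nulls, and
   2-D cluster-based permutation inference.

Because the simulator's generative couplings are known exactly, every
analysis can be validated against ground truth: effects must appear where
couplings exist and must vanish where they do not.

## The task and its constants

Each stimulus is eight colored elements whose color values lie on the
linear RGB path from red `(1,0,0)` to blue `(0,0,1)`; position `C` on the
path sets the mean (0.5 is the category boundary) and `V` the variance
across elements. The design crosses mean level (`C` in {0.450, 0.474,
0.526, 0.550}, i.e. boundary distances 0.05 and 0.026), variance level
(`V` in {0.0333, 0.1000}), color, and trial type (75% free-choice, 25%
no-choice), balanced exactly within each of 10 blocks of 64 trials.
On free-choice trials the observer may pay 1 point to see an easier
version of the stimulus (`C' = C ± 0.01` away from the boundary,
`V' = V − 0.0167`) before the final decision; correct final answers earn
5 points, errors lose 5, and 650 points convert to £1. Confidence is
reported on a signed −50..50 scale (0 excluded) and standardized per
participant and block. Between blocks, a staircase nudges the low-mean
`C` level by 0.0025/0.0012/0.0005 when the inverse-efficiency-score gap
(median correct RT / accuracy) between the low-mean/low-variance and
high-mean/high-variance cells exceeds 100/50/10 in absolute value, in the
direction that closes the gap. All of these constants are encoded in
`makeDesign()`, `makeEasier()`, `staircaseUpdate()` and `scoreSession()`
and checked exactly by the test suite.

```{r design}
d <- makeDesign(n_blocks = 2, seed = 1)
table(d$trial_type, d$block)
sort(unique(round(d$C, 3)))
```

## The observer model

The task description does not pin down an observer, so the package uses
the simplest model that produces the behavioral structure the analyses
require. On each trial the observer draws internal evidence
`e ~ Normal(C − 0.5, sigma(V))` with `sigma(V) = sigma0 + sigma_v *
sqrt(V)` (noise grows with stimulus variance), answers with `sign(e)`,
and maps evidence magnitude to confidence through a saturating
`50 * tanh(gain * |e| + metacognitive noise)` rounded to the integer
scale. The decision to sample more evidence is a threshold on noisy
pre-sampling confidence plus a participant-specific bias: this makes
confidence *negatively* predict seeking, the coupling the study design
assumes, with large between-participant variation in seeking rates. After
sampling, the easier stimulus contributes a second evidence draw that is
added to the first before the final decision. RTs are shifted log-normal
with location decreasing in `|e|`.

Defaults (`observerParams()`) were chosen once to put primary accuracy in
the 65–80% range the staircase targets (e.g. boundary distance 0.05 over
`sigma ≈ 0.06` gives ~79% in the easiest cells) and mean seeking rates
near 40–50% with wide participant spread. The mapping from evidence to
the confidence scale is unspecified in the task description; any monotone
map works, and the saturating map was chosen so that ratings use the full
scale without piling up at the ends.

Reported confidence on see-again trials reflects the combined evidence,
while the seeking decision and the EEG components can only depend on the
*pre-sampling* state; the trial table therefore carries both
(`confidence_abs` and `confidence_pre`). On no-choice trials — the only
trials on which confidence enters the analyses — the two coincide.

## The EEG forward model

`simulateEEG()` builds one continuous multichannel signal per trial on
the stimulus clock and cuts it on three clocks (stimulus, response,
choice), so realignment between clocks is physically consistent and
`realignEpochs()` can be validated exactly against the simulator's native
cuts. The signal is

* a P3: unit-norm centroparietal topography (Gaussian bump over 2-D
  electrode positions centred at CPz) times a truncated-Gaussian kernel
  supported 300–600 ms post-stimulus, amplitude
  `alpha0 + alpha1_p3 * confidence_z`;
* a Pe: the same style of topography and a kernel supported 250–700 ms
  post-response, amplitude `alpha0 − alpha1_pe * confidence_z` (larger
  when confidence is low), plus optionally `beta_difficulty_pe` times a
  centered stimulus-difficulty code for confound analyses;
* additive Gaussian noise, white in time, with channel covariance
  `noise_sd^2 * ((1 − rho) I + rho K)`, `K` a squared-exponential kernel
  over electrode distances.

Amplitudes are in microvolts; with the defaults (`alpha0 = 4`,
`alpha1_pe = 3`, `noise_sd = 8`, window averaging over ~27 samples at
250 Hz) the single-trial discriminability of a median confidence split is
Az ≈ 0.7–0.75 at the Pe peak, the regime in which published single-trial
Pe decoding operates and which the package's structure-recovery checks
presuppose. The default sampling rate is 250 Hz (a desk-scale choice;
recording hardware rates are configurable). Event times are snapped to
the sample grid so that cross-clock slicing is exact.

What the generator deliberately does **not** emulate: temporally
autocorrelated background rhythms, eye blinks and other artifacts
(rejection is exercised with injected extreme values instead), volume
conduction beyond the smooth topographies, and latency jitter of the
components. Passing tests therefore validate the statistical machinery
and its calibration, not robustness to every property of real recordings.

## Preprocessing conventions

Stimulus-locked epochs span −100..1000 ms and are baselined −100..0 ms
pre-stimulus; response-locked epochs span −100..700 ms with a
−100..0 ms pre-response baseline (or a kept pre-stimulus baseline after
realignment — `realignEpochs()` never recomputes an applied baseline);
choice-locked epochs span −700..100 ms. Trials containing any sample at
or beyond ±200 µV are excluded. Trials whose realigned window exceeds the
recorded epoch are dropped and logged rather than padded. Confidence
z-scoring uses the sample (n−1) standard deviation; degenerate
participant-by-block cells get z = 0 and a flag. Median splits send
values above the median to "high", below to "low", and alternate ties so
the imbalance never exceeds the tie count.

## ERP statistics

`conditionERP()` averages single trials per condition at one electrode
(CPz by default). Condition differences are tested with a within-subject
cluster-based permutation test (`clusterPermutation1D()`): per time
sample a paired two-tailed t across subjects, elements with p < 0.05
collected into temporally contiguous clusters separately by sign, cluster
mass = sum of |t|, and a max-mass null from within-subject condition
flips. With 12 or fewer subjects all `2^S` sign patterns are enumerated
(the test is then exact); otherwise 1000 Monte-Carlo flips are drawn and
p = (b + 1)/(n + 1). `timewiseRegression()` fits per-subject OLS of
single-trial amplitude on stimulus mean, variance, their interaction and
confidence at each sample; group inference applies the same 1-D cluster
machinery to the per-subject t values against zero. The group stage is a
one-sample sign-flip test — the standard reading of a cluster test on
per-subject regression statistics.

## The decoding chain

`slidingWindows()` averages each channel within 106-ms windows moved in
10-ms steps (converted to whole samples at the epoch's sampling rate).
At each training window a **linear-derivation spatial filter** is fitted:
logistic regression on the window-averaged channel vector, whose weights
project a trial to a scalar component amplitude. Performance is **Az**,
the ROC area of the projections (ties count one half; equal to
pair-counting, which the tests verify against an O(n²) oracle).

*Within-condition* (`tgmWithin()`): stratified 10-fold cross-validation;
per repeat, held-out projections are pooled over folds and scored with a
single Az per (train, test) window pair; Az is averaged over repeats
(100 by default). Training windows can be truncated (e.g. at 400 ms
post-stimulus) to keep post-response activity out of stimulus-locked
training data on short-RT trials.

*Across-condition* (`tgmAcross()`): classifiers trained on high- vs
low-confidence no-choice trials (correct on both decisions) are tested on
see-again vs respond free-choice trials (correct primary decisions), so
training and testing data never overlap. Each of 1000 iterations (40 in
the desk-scale worked example) subsamples both sets to equal class
counts; Az is averaged over iterations. Balancing both sets resolves an
ambiguity in how the balanced resampling is described: balancing only the
training set would leave the test-set base rate to bias Az through the
pooled ranking, so both are balanced here.

*Null matrices* (`nullMatrices()`): the same computation with labels
randomized per iteration, averaged — a per-subject estimate of the
chance surface over the full 2-D grid. *Inference*
(`clusterPermutation2D()`): per pixel, a paired t of true vs null across
subjects; pixels with two-tailed p < 0.01 are clustered under
8-connectivity (cardinal or diagonal neighbours), masses are sums of |t|,
and the max-mass sign-flip null (enumerated when feasible) yields
cluster p values. *Controls*: `residualizeEpochs()` replaces the EEG by
OLS residuals of mean, variance and their interaction per channel and
sample before decoding; `closestCluster()` and `comparePeakClusters()`
implement the peak-centred comparison of pre- versus post-response
decoding (matched pixel counts around the peak, or fixed 3×3…9×9
squares, clipped at matrix edges with a warning).

### Regularization

The logistic fit carries an L2 ridge. For the standalone
`trainSpatialFilter()` the default penalty is a small constant (1),
enough to keep separable problems finite while leaving the
maximum-likelihood direction intact — on a large Gaussian toy the learned
weights align with the closed-form LDA direction `Σ⁻¹δ` to cosine
> 0.99. Inside the cross-validated pipeline the trial counts are tens to
a few hundreds against 32 correlated channels, where near-ML fits
overfit badly; `decodingConfig()` therefore uses a *scale-aware* ridge —
penalty = `lambda` × training-trial count × mean feature variance — so
that shrinkage is comparable across window grids, trial counts and
amplitude scales. The default `lambda = 2` sits on the performance
plateau in held-out simulation and pushes the solution toward the
(whitened) class-mean-difference direction, a standard robust regime for
event-related component decoding.

### Randomness and determinism

Every stochastic step (design order, stimulus draws, observer noise, EEG
noise, fold assignment, balancing, label shuffles, Monte-Carlo sign
flips) takes an explicit seed and restores the caller's RNG state, so
identical seeds give bit-identical tables, epochs and matrices. Where a
sign-flip null can be enumerated (≤ 4096 patterns) no randomness is used
at all and the permutation p values are exact.

## Calibration and problem sizes

The test suite validates calibration at reduced sizes chosen to keep a
full run in a few minutes on one CPU: type-I error of the 1-D and 2-D
cluster tests is estimated over 300 pure-noise simulations with 8
subjects (200-sample waveforms / 15×15 matrices) and must not exceed
0.05 plus twice its Monte-Carlo standard error; shuffled-label decoding
must stay within 0.48–0.52 after averaging null iterations. The
structure-recovery check simulates 8 subjects × 320 trials with
post-response-only confidence coupling and runs the full pipeline at a
20-ms window step with 3 cross-validation repeats, 40 balancing
iterations and 6 null iterations: it must find significant post-response
within-condition clusters for confidence and for seeking and a
significant across-condition cluster peaking post-response, no
stimulus-locked clusters, an across-condition cluster that survives
difficulty residualization when a difficulty coupling is added, and
chance-level transfer with no cluster when the confidence coupling is
removed. These sizes are the package's desk-scale defaults for worked
examples; the full study-scale settings (10 blocks, 100 repeats, 1000
iterations and permutations) remain the function defaults.

## Known limitations

* Temporally white noise makes single-sample statistics better behaved
  than on real EEG, where autocorrelation inflates cluster sizes; the
  cluster tests themselves are calibrated either way, but extents should
  not be over-interpreted.
* The observer has no sequential dynamics (no drift-diffusion RT model,
  no confidence leak across trials); RTs and confidence are conditionally
  independent given the evidence draw.
* Mixed-model fitting of the behavioral condition frame is delegated to
  standard packages; `exportModelFrame()` only prepares the
  8-cells-per-participant input with low-variability/high-mean reference
  coding.
* Single-subject inference is out of scope: all cluster tests are
  group-level.
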