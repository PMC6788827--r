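# seekEEG

Simulation and time-resolved decoding of confidence-driven
information-seeking from scalp EEG.

## What this package is for

When a perceptual decision is made with low confidence, paying a small
cost to sample more evidence before committing is often worth it. A
central question in the cognitive neuroscience of metacognition is
whether the *neural* representation of decision confidence — in
particular the post-decisional centroparietal error positivity (Pe),
whose amplitude scales inversely with confidence — is the signal that
drives these information-seeking choices. The decisive test is
**across-condition decoding**: train a multivariate classifier to
discriminate high- vs low-confidence EEG epochs on trials where the
observer was forced to respond, then test it on separate free-choice
trials where the observer could ask to see the stimulus again. Transfer
above chance, confined to the post-response window, indicates a shared
neural code linking confidence to information seeking.

seekEEG provides both sides of that experiment in one tested package:

* **Forward simulation** — a color-mean discrimination task (8 elements
  on the red–blue RGB path; mean levels C ∈ {0.450, 0.474, 0.526,
  0.550}, variance levels V ∈ {0.0333, 0.1000}; 10 blocks × 64 trials,
  75% free-choice, exactly balanced), a Gaussian-evidence observer whose
  confidence negatively drives seeking, an inverse-efficiency staircase
  (steps 0.0025/0.0012/0.0005 at IES-gap thresholds 100/50/10), point
  scoring (+5/−5/−1, 650 points = £1), and 32-channel EEG epochs with
  confidence-coupled P3/Pe components in spatially correlated noise —
  cut consistently on stimulus, response, and choice clocks.
* **Analysis** — baseline correction, cross-clock realignment, ±200 µV
  rejection, per-block confidence z-scoring, median splits; condition
  ERPs and within-subject 1-D cluster-based permutation tests (cluster
  mass = Σ|t|, sign-flip max-mass null, exact enumeration up to 12
  subjects); time-resolved single-trial regression; and the decoding
  chain: 106-ms sliding-window linear-derivation logistic spatial
  filters, Az (ROC area) scoring, within-condition temporal
  generalization with repeated stratified 10-fold CV, across-condition
  transfer with balanced resampling, shuffled-label null matrices, 2-D
  cluster permutation inference under 8-connectivity, difficulty
  residualization, and peak-centred cluster comparisons.

The central statistic throughout is the temporal-generalization matrix
`Az(t_train, t_test)`, compared against per-subject null matrices with a
paired-t cluster-mass permutation test (element p < .01, cluster
p < .05).

## Worked example

One simulated participant (5 blocks = 320 trials), behavioral summary,
and within-condition decoding of confidence from response-locked epochs:

```r
library(seekEEG)

design <- makeDesign(n_blocks = 5, seed = 7)
trials <- simulateObserver(design, seed = 8)
summarizeConditions(trials)[, c("mean_level", "var_level", "acc_primary",
                                "p_see_again", "mean_conf_z", "ies")]
#>   mean_level var_level acc_primary p_see_again mean_conf_z  ies
#> 1       high      high       0.662       0.450       0.101  928
#> 2       high       low       0.800       0.483      -0.438  801
#> 3        low      high       0.600       0.400      -0.496 1053
#> 4        low       low       0.625       0.583      -0.980  992

scoreSession(trials)
#> session: 635 points -> GBP 0.98

epochs <- simulateEEG(trials, eegParams(alpha1_p3 = 0), seed = 9)
resp <- rejectExtreme(baselineCorrect(epochs$response, c(-100, 0)))$epochs
keep <- trialIndex(resp)
nc <- which(trials$trial_type[keep] == "no-choice" &
            trials$primary_correct[keep] == 1 & trials$final_correct[keep] == 1)
labels <- medianSplit(trials$confidence_z[keep][nc])

cfg <- decodingConfig(step_ms = 20, n_repeats = 3, n_null_iters = 6)
tgm <- tgmWithin(resp[nc], labels, cfg, seed = 10)
tgm
#> DecodingMatrix (within-condition, response-locked): 36 train x 36 test windows
#>   Az range: 0.181..0.825 (grand mean 0.638)

null <- nullMatrices(resp[nc], labels, cfg, seed = 11)
d <- diag(azMatrix(tgm)); tt <- trainTimes(tgm)
mean(d[tt > 250 & tt < 700])   # diagonal Az in the Pe window
#> 0.727  (shuffled-label null: 0.537)
```

Accuracy, RT and confidence scale with the stimulus mean and variance;
seeking is most frequent in the hardest cell; and confidence is
decodable from this subject's post-response epochs well above the
shuffled-label chance level — within-subject matrices like `tgm` and
`null`, stacked over subjects, feed `clusterPermutation2D()` for group
inference, and `tgmAcross()` runs the confidence → seeking transfer the
same way. Behavioral measures feed `exportModelFrame()` for
condition-level mixed-model analyses in standard packages.

## Package layout

| Where | What |
| --- | --- |
| `R/design.R`, `R/observer.R` | task design, stimuli, observer, staircase, scoring |
| `R/eeg-sim.R`, `R/montage.R` | EEG forward model, montage, topographies |
| `R/preprocess.R` | baseline, realignment, rejection, z-scoring, median split |
| `R/erp.R`, `R/clusters.R` | ERPs, regression, 1-D/2-D cluster permutation tests |
| `R/decoding.R` | spatial filters, Az, TGMs, nulls, residualization, peak comparisons |
| `R/summaries.R`, `R/io.R` | behavioral summaries, plain-text containers |
| `vignettes/confidence-seeking-eeg.Rmd` | the methods vignette |
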