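# eegbold

Predicting regional fMRI BOLD activity from simultaneously recorded EEG.

EEG gives millisecond-scale electrical activity at the scalp; fMRI gives
spatially resolved but hemodynamically delayed BOLD signal. If regional
BOLD activity can be predicted from EEG band powers, wearable EEG devices
could approximate fMRI-grade readouts. `eegbold` implements two
complementary strategies for this prediction problem and the statistical
machinery to evaluate them, plus a synthetic EEG-fMRI study generator so
the full pipeline runs and is tested without any external data. It is
aimed at neuroimaging methods researchers and at anyone who wants a
worked, tested harness for EEG-to-fMRI decoding experiments.

## What it computes

**Targets.** Per atlas region r, the BOLD series is ROI-averaged,
linearly detrended, z-normalized and outlier-corrected (|z| > 3 replaced
by the previous scan). The classification target at scan t is
`y_t = 1[b_t − b_{t−1} ≥ 0]` (direction: increase/decrease); the
regression target is `b_t` itself.

**Features.** EEG is cut into TR-aligned 2-s segments; per segment and
channel, Welch band powers are integrated over delta (1–4 Hz), theta
(4–8), alpha (8–12), sigma (12–16), beta (16–30) and gamma (30–40 Hz),
z-normalized per channel-band (|z| > 4 replaced by the previous segment).
The feature vector at scan t concatenates band powers at scans
t−5 … t — a 10-s window spanning the hemodynamic response peak.

**Strategy 1 — supervised models.** A uniform fit/tune/predict adapter
over logistic/linear regression, k-NN, decision tree, random forest, RBF
SVM, gradient boosting, and four neural families (MLP, 1-D CNN on raw
EEG, GRU, transformer encoder) trained with Adam, binary cross-entropy or
MSE, and early stopping. Evaluation uses a threefold condition rotation
within each subject: each recording condition serves exactly once as
train and once as test set (the third is left out, or used as validation
for the neural families).

**Strategy 2 — prompted text-generation backends.** Deterministic prompt
builders phrase the same direction-prediction task in natural language
(single-channel, chain-of-thought, multimodal, and five-channel
hierarchical modes), a strict parser maps responses to
increase/decrease/invalid via the inflected keyword stems
`increas-`/`decreas-`, and deterministic mock backends make the whole
branch testable offline.

**Statistics.** Per subject-region pair the model metric is compared to a
constant baseline (always-increase for accuracy; constant zero for MAE)
with a one-sided Wilcoxon signed-rank test (exact null up to 25
informative pairs, computed by convolution), matched-pairs rank-biserial
correlation and common-language effect size, pairwise model-vs-model
tests, and per-ROI tests. The prompting branch is scored against a
resampled baseline (labels redrawn from the empirical truth
distribution) with iterated McNemar tests (exact doubled binomial tail up
to 25 discordant pairs) over thousands of resampling iterations.

**Synthetic studies.** `generateStudy()` emulates a 9-subject,
3-condition neurofeedback study (TR 2 s, 64-channel EEG at 200 Hz, 49
cortical regions, alternating 20-scan rest/task blocks): AR(1) band-power
latents with block modulation, per-subject sparse coupling weights,
causal double-gamma HRF convolution into BOLD, linear drift, noise, rare
outliers, and optionally raw EEG whose Welch band powers recover the
latents. Hierarchical seed substreams make every session reproducible and
stable under study growth.

## Worked example

```r
library(eegbold)

cfg <- syntheticConfig(nSubjects = 3, nRegions = 8, nChannels = 4,
                       nScans = 120, blockLenScans = 20,
                       couplingGain = 3, seed = 42)
study <- generateStudy(cfg)
report <- runExperiment(study, list(
  modelSpec("svm", "classification"),
  modelSpec("rforest", "classification"),
  modelSpec("knn", "classification", list(k = 5))))
report
#> StatReport: 216 pairs, 3 models, 0 exclusions
#>     model nPairs meanMetric seMetric meanBaseline        p   rbc cles
#> 1     svm     72      0.651  0.00600        0.502 8.43e-14 1.000 1.00
#> 2 rforest     72      0.687  0.00667        0.502 8.41e-14 1.000 1.00
#> 3     knn     72      0.573  0.00698        0.502 2.80e-10 0.859 0.84
```

Each row pools the 72 subject-region pairs (3 subjects x 8 regions x 3
rotation iterations): `meanMetric` is the mean test accuracy,
`meanBaseline` the accuracy of constantly predicting an increase (~0.50
on balanced targets), `p` the one-sided Wilcoxon signed-rank p-value
against that baseline, and `rbc`/`cles` the matched-pairs effect sizes.
With coupling gain 3 all three models detect the EEG-to-BOLD coupling
decisively. `roiTable(report)` gives the same test per region;
`pairwiseTests(report)` compares models head to head.

The prompting branch with a deterministic oracle backend:

```r
map <- readRegionChannelMap()
bp  <- matrix(rnorm(12), 6, 2, dimnames = list(defaultBands()$name, NULL))
b   <- buildPrompt("single_channel", map, bp, "Frontal Pole")
truths <- rep(c("increase", "decrease"), 10)
ev <- runFoundationEval(rep(list(b), 20), mockBackendOracle(truths), truths,
                        resampledBaselineConfig(nIterationsMcnemar = 1000,
                                                seed = 1))
#> oracle backend: accuracy 1.00, invalid 0.00, median McNemar p 0.002
```

## Vignette

`vignettes/eegbold-methods.Rmd` documents the model and its assumptions,
the generator's design and what it does and does not emulate, all
numerical choices and defaults, and known limitations (including a
documented conservativeness of the null calibration that follows from
the tie-labeling and outlier-replacement conventions).
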