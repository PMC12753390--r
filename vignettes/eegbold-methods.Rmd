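---
title: "eegbold: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{eegbold: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind it, and the choices made where the design was
genuinely open.

## The prediction problem

Simultaneous EEG-fMRI recordings measure the same brain with
complementary instruments: EEG resolves fast electrical dynamics at the
scalp, fMRI resolves slow, spatially localized hemodynamics. The package
formulates EEG-to-fMRI prediction per cortical region in two ways:

* **classification** — does the normalized regional BOLD signal increase
  or decrease between two successive scans (`y_t = 1[b_t - b_{t-1} >= 0]`)?
* **regression** — what is the normalized BOLD value `b_t` itself?

The predictors are normalized EEG band powers over the scan at t and the
5 preceding scans. At a repetition time of 2 s that window reaches 10 s
back, which covers the peak latency of the hemodynamic response function
(HRF): EEG events that drove the BOLD change should still be inside the
window. The lag depth is configurable (`nLags`), and the first `nLags`
scans of every session are dropped rather than zero-padded, so each
sample is built from fully observed history.

## Preprocessing

Both modalities go through the same primitives (`SeriesMatrix` is the
shared container):

1. **Drift removal (BOLD only).** Per region, the least-squares straight
   line over scan index is subtracted. Scanner drift is slow and roughly
   monotone over a session; a linear term is the minimal model for it.
   A numerically exact fit (residual SD below 1e-10 of the input SD) is
   snapped to zero so that downstream normalization treats the column as
   genuinely constant.
2. **Z-normalization.** Per unit (region, or channel-band pair),
   subtract the mean, divide by the population SD (`ddof = 0`; the
   sample SD is available via `ddof = 1`). The population convention is
   deterministic and scale-exact for short series — `c(1, 3)` maps to
   `c(-1, 1)`. Constant columns cannot be scaled; they become all zeros
   and carry a `degenerate` flag rather than NaNs.
3. **Outlier replacement.** Entries beyond a threshold (|z| > 3 for
   BOLD, |z| > 4 for band powers) are replaced by the value at the
   previous time point. Flags are computed once, on the input; the
   replacement cascades left to right, so consecutive outliers inherit
   the last clean value. A flagged first time point has no predecessor
   and is left unchanged (still flagged and counted). There is no
   re-detection and no re-normalization after replacement: the recorded
   proportions refer to the original series, and the order
   normalize-then-replace is fixed. Previous-value replacement is
   deliberately conservative — it corrects rare spikes without
   fabricating temporal structure.

The EEG normalization is applied per channel-band pair (not per channel
pooling bands): bands live on very different power scales, and pooling
would let delta dominate every z-score. This is configurable at the
`SeriesMatrix` level if a user wants the pooled convention.

## Band powers

EEG is segmented into half-open, TR-aligned windows (`[t*TR, (t+1)*TR)`,
trailing samples dropped). Per segment and channel the power spectral
density is estimated by Welch's method — 1-s Hamming windows at 50%
overlap, mean across windows — and integrated over delta (1–4 Hz), theta
(4–8), alpha (8–12), sigma (12–16), beta (16–30) and gamma (30–40 Hz)
with the trapezoid rule on the closed `[low, high]` frequency grid.
Shared band edges (4, 8, 12, 16 Hz) receive half weight in each adjacent
band, so total power is conserved and nothing is double-counted; the
closed grid is what makes the analytic checks come out right (a 10-Hz
sinusoid of amplitude a recovers alpha power a²/2; flat noise of
one-sided level p gives beta power p x 14 Hz). Powers are absolute, in
µV²; the subsequent z-scoring removes the scale anyway. The 1-s window
gives 1-Hz resolution, the finest that fits three averaged windows into
a 2-s segment; all Welch parameters are arguments.

## The synthetic study generator

`generateStudy()` emulates the structure of a multi-subject neurofeedback
study: 9 subjects x 3 conditions (eegfmriNF, eegNF, fmriNF), TR 2 s,
64-channel EEG at 200 Hz, 49 cortical regions, 200 scans per session in
alternating 20-scan rest/task blocks. The generative model:

* **Band-power latents** are stationary AR(1) series (coefficient 0.5,
  unit marginal variance) per channel-band — enough autocorrelation to
  look physiological without committing to a spectral model. Task blocks
  add a mean shift (`blockAmp`, default 1) to alpha and beta of the
  first half of the montage, a motor-imagery-like desynchronization
  proxy.
* **Coupling.** Each region couples to 3 random channel-band pairs with
  standard-normal weights, drawn once per subject and shared across that
  subject's conditions — cross-condition generalization is only possible
  because the coupling is a property of the subject, not the session.
* **BOLD.** The coupling-weighted latent sum is convolved causally
  (truncated at scan 0, no pre-session history) with a double-gamma HRF
  (peak delay 6 s, undershoot delay 16 s, dispersions 1 s, undershoot
  ratio 1/6, 32-s support, unit peak; the density form puts the mode at
  5 s, inside the expected 4–7 s range), scaled by `couplingGain`, plus
  a linear drift with per-region random slope (`driftSlopeSd = 0.01`
  per scan, i.e. about 2 SD over a 200-scan session) and white noise
  (`noiseSd = 1`).
* **Outliers** are injected in both modalities at rate
  `outlierRate = 5e-4` as 6-SD spikes, so the detection thresholds
  catch them.
* **Raw EEG** (optional) realizes each scan as a sum of band-centre
  sinusoids whose squared amplitudes equal
  `2 * max(latent + rawPowerOffset, 0)` plus broadband noise; Welch
  analysis then recovers `latent + rawPowerOffset`. The offset (default
  5 µV²) exists because the latents are zero-mean while physical powers
  are non-negative.
* **Seeds.** One master seed; every (subject, condition, stage) draws
  from its own hashed substream, so regenerating with more subjects
  never changes existing sessions.

What the generator does **not** emulate: EEG artifacts (gradient,
ballistocardiogram), head motion, volumetric smoothing, spatial
correlation between regions, condition-specific coupling, non-linear or
state-dependent hemodynamics. Passing tests on synthetic studies
therefore demonstrate that the pipeline recovers the embedded linear,
HRF-delayed coupling under realistic noise — not that real EEG predicts
real BOLD.

## Models

Classical families are thin adapters over their standard packages
(`glm`, `lm`, `class::knn`/`caret::knnreg`, `rpart`, `ranger`,
`e1071::svm` with an RBF kernel, `xgboost`). `tuneModel()` grid-searches
a hyperparameter (the number of neighbours for k-NN, the depth for the
decision tree) on a validation set and breaks exact ties toward the
simplest model.

The neural families run on a compact reverse-mode autodiff engine inside
the package (matrix tape, Adam, mini-batches of 32, early stopping on
validation loss with patience 10, at most 200 epochs, binary
cross-entropy or MSE, ReLU hidden activations). Gradients of every
architecture are validated against finite differences in the test suite.
Default architectures are this package's choices, all configurable:

* MLP: two hidden layers (64, 32);
* GRU: one layer, width 64, over the 6 time steps;
* transformer: 2 pre-norm encoder blocks, 4 heads, model width 32,
  sinusoidal positional encoding, mean pooling over tokens;
* 1-D CNN: three convolution blocks with average pooling and global mean
  pooling, EEG channels as input channels. On the raw-EEG path the
  kernels are (7, 5, 3) over the sample axis; on the lagged band-power
  path the time axis has only 6 steps, so the defaults shrink to
  (3, 3, 2) without pooling.

The CNN's weight sharing and global pooling presuppose
translation-invariant structure along its time axis; the direction
target is driven by position-specific lags, which is why the CNN is kept
as a control rather than a contender — consistent with how it behaves.

Every fit is deterministic given the spec seed (single-threaded ranger
and xgboost, seeded initialization and batching).

## Cross-validation and statistics

`makeCvPlan()` rotates the three conditions cyclically: iteration i
trains on condition i and tests on condition i+1 (mod 3); each condition
is used exactly once for training and once for testing. The third
condition is left out for classical models and is the validation set for
neural ones. The rotation direction (i trains, i+1 tests) is a fixed
convention; any direction satisfies the once-each property.

Per subject-region pair and iteration, the model metric (accuracy or
MAE) is compared against the constant baseline: always predict increase
(classification), always predict 0 (regression; the mean of a z-scored
signal). The default 9 x 49 design gives 441 pairs per iteration and
1323 overall.

The statistical layer is authored in the package and cross-checked in
the tests against exhaustive enumeration and the reference R
implementations:

* **One-sided Wilcoxon signed-rank.** Zero differences are discarded
  (classic convention). Up to 25 informative pairs, the exact null
  distribution of the rank sum is computed by convolving the doubled
  midranks over all sign assignments; beyond that, a normal
  approximation with continuity and tie corrections. Reported alongside:
  matched-pairs rank-biserial correlation `(W+ - W-)/(W+ + W-)` and the
  common-language effect size (proportion of favorable pairs, ties
  counting one half, over all pairs).
* **Iterated McNemar against a resampled baseline.** For the prompting
  branch, baseline predictions are redrawn per iteration from the
  empirical truth distribution (invalid predictions excluded
  beforehand); the 2x2 correctness table is pooled over items and the
  McNemar p computed exactly (doubled binomial tail, capped at 1) up to
  25 discordant pairs, else via the continuity-corrected chi-square. The
  default 10,000 iterations (1,000 for the Wilcoxon variant) summarize
  into a median p, the proportion of significant iterations, and a
  20-bin histogram on [0, 1].
* **Per-ROI tests** are reported raw; a Benjamini-Hochberg column is
  added as an extra, clearly labeled `pBH`.

## Prompting branch

Prompt builders render fixed templates for five modes (single-channel,
the two chain-of-thought steps, multimodal with an attachment slot, and
the five-channel hierarchical mode), with the region and electrode in
plain text and band powers as a dictionary-like structure
(`Beta (16–30 Hz): [0.12, -0.34, ...]`, two decimal places by default;
the five-channel mode nests the band dictionaries under electrode
labels). The shipped region-to-channel table is proximity-based
(e.g. Frontal Pole to Fpz), covers a subset of cortical regions, and is
meant to be replaced wholesale.

The parser matches the inflected stems `increas-`/`decreas-`
case-insensitively; exactly one family present yields that label, zero
or both yield `invalid`. It is total — every string maps to exactly one
of the three labels — and invalid predictions are excluded from scoring
with their proportion reported, the evaluated and invalid counts always
summing to the bundle count. Real text-generation backends plug in
through a one-function contract (prompt text in, response text out); the
shipped backends are deterministic mocks (oracle, constant, resampling
null, and an invalid-injecting wrapper), and a backend exception is
recorded as an invalid prediction rather than raised.

## Calibration findings and a known conservativeness

`calibratePipeline()` reruns the full pipeline (generation,
preprocessing, features, rotation CV, model, Wilcoxon vs baseline) on
replicate scaled-down studies — 3 subjects, 8 regions, 2 channels, 120
scans, k-NN as a fast training-noise-free family — and reports each
replicate's p-value. The test suite uses 300 replicates for the null
(coupling 0) and 100 per gain level for the power curve; the acceptance
script uses 200 and 100. These sizes were chosen to keep Monte-Carlo
error a fraction of the tolerances they are checked against.

Two properties emerge, both computed by the tests and the acceptance
script:

* **Power behaves.** The rejection rate is monotone in the coupling
  gain, and at gain 4 the RF, SVM and MLP pooled accuracies sit well
  above the constant baseline.
* **The null is conservative, and the package documents why.** Under
  zero coupling the one-sided Wilcoxon rejects at about 1–3% rather than
  the nominal 5%. This is a structural property, not a test defect:
  previous-value outlier replacement creates exact zero differences
  between consecutive scans at a small rate τ (≈0.3%: natural |z| > 3
  crossings plus injected outliers), the tie convention labels those
  scans "increase", and the baseline constantly predicts increase — so
  the baseline's expected accuracy is 0.5 + τ/2 while a balanced model's
  stays at 0.5 (E[d] = −τ(1−p̄) for a model predicting increase at rate
  p̄). Scoring with tie scans excluded restores the nominal rate, and a
  sign test or t-test on the same pairs is equally conservative, while
  the in-package Wilcoxon agrees exactly with enumeration and with
  `stats::wilcox.test`. The practical reading: significance claims made
  against this baseline are slightly conservative, which errs on the
  safe side.

## Numerical choices collected

* Population-SD z-scoring (`ddof = 0`), configurable.
* Exact-fit snap-to-zero threshold in detrending: residual SD below
  1e-10 of the input SD.
* Detrended columns are orthogonal to `[1, t]` to ~1e-9.
* Welch: 1-s Hamming, 50% overlap, mean across windows; trapezoid on the
  closed band grid.
* Ties in the direction label (Δ = 0) → increase.
* Wilcoxon exact branch up to n = 25 informative pairs; zero differences
  discarded; continuity correction 0.5 in the normal branch.
* McNemar exact branch up to b + c = 25; p capped at 1; b = c gives
  p = 1.
* Early stopping: patience 10, max 200 epochs, batch 32, Adam at 1e-3.
* Grid-tuning ties break toward the smallest hyperparameter value.
* Empty atlas regions yield a sentinel zero column plus a warning (and
  an `emptyRegions` attribute), not an error, so partial-coverage
  volumes still run.

## Limitations

The synthetic generator is linear and stationary; none of the results on
it transfer claims about real data. Cross-subject generalization is out
of scope (the rotation is within-subject). The neural defaults are small
and are tuned for the scaled problem sizes of the test suite, not for
real studies. The prompting branch ships only mock backends; hooking up
a real language model is the user's integration, and the generation
parameters of such models are outside the package's control.
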