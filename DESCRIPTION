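Package: eegbold
Title: Predicting Regional BOLD Activity from EEG Band Powers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting regional fMRI BOLD activity from
    simultaneously recorded EEG. Provides preprocessing primitives shared by
    both modalities (z-normalization, linear drift removal,
    previous-value outlier replacement), Welch band-power extraction on
    scan-aligned EEG segments, atlas ROI averaging, lagged feature and
    direction/value target construction, a uniform train/predict adapter
    over classical and neural model families, a condition-rotation
    cross-validation harness with a paired statistical layer (one-sided
    Wilcoxon signed-rank with exact small-sample null, iterated McNemar
    tests against a resampled baseline, rank-biserial and common-language
    effect sizes, per-ROI tests), and a prompt-construction, response-parsing
    and evaluation harness for text-generation backends with deterministic
    mocks. A synthetic multi-subject EEG-fMRI study generator with known
    hemodynamically delayed coupling makes the full pipeline testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    class,
    caret,
    rpart,
    ranger,
    e1071,
    xgboost,
    RNifti,
    pracma
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
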