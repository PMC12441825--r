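Package: expectdecode
Title: Probabilistic Cueing Designs and Decoding of Expectancy from Multichannel Brain Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing cross-domain probabilistic cueing
    experiments: counterbalanced 2x2 expectancy trial schedules with
    confound-matching subsampling; synthetic generators for orientation-tuned
    multichannel EEG epochs, continuous-reproduction behaviour and pupil traces
    with known ground truth; an inverted encoding model with
    shrinkage-regularised spatial filters for per-timepoint orientation
    decoding; von Mises plus uniform mixture modelling of reproduction errors;
    2x2 repeated-measures ANOVA with partial eta squared and JZS Bayes factors;
    cluster-mass permutation statistics for time series; time-resolved linear
    discriminant analysis of trial expectancy; and deterministic pupillometry
    and EEG epoch preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
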