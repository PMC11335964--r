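Package: sherpa
Title: SHAP-Driven Event-Related Potential Analysis for Epoched EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains a convolutional classifier to separate experimental
    conditions from epoched EEG, attributes its decisions to (electrode,
    time) features with expected-gradients SHAP values, and distills the
    attributions into objective ERP coordinates: important time windows
    and ranked electrode sets.  Ships the two standard comparator
    analyses (spatio-temporal cluster-based permutation test on the
    dependent F statistic, and a conventional repeated-measures ANOVA on
    mean amplitudes), plus a seedable synthetic ERP generator so the
    whole pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
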