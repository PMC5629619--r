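Package: linkdrp
Title: Link-Prediction Approach to Cancer Drug Sensitivity Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts in vivo drug sensitivity of tumors from cancer cell-line
    expression profiles and IC50 drug responses by recasting the regression
    task as link prediction. Each sample is represented as the concatenation
    of its expression profile with a synthetic profile interpolated toward a
    nearest neighbor; training cell lines are filtered by distance-to-test
    weighting combined with a relaxed query-by-committee selection loop, and
    influential feature columns can be selected by CUR statistical leverage
    scores. Includes ridge and support vector regression learners, an
    AUC/MAUC evaluation harness with Wilcoxon signed-rank and t-test
    comparisons, and a seeded synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
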