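Package: icgperf
Title: Quantitative Perfusion Analysis of ICG Fluorescence Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies indocyanine green (ICG) fluorescence angiography of
    bowel perfusion from time-fluorescence intensity curves: bolus onset
    detection and extraction of the kinetic parameters T_MAX, T_1/2MAX,
    perfusion time ratio, F_MAX and slope, including region-of-interest
    time-series extraction from fluorescence frame stacks. Derives "safe"
    parameter cutoffs against hyperspectral tissue oxygen saturation (StO2)
    by inverse linear and quadratic regression with confidence intervals of
    the mean response, evaluates those cutoffs diagnostically (contingency
    tables, sensitivity/specificity/PPV/NPV/accuracy with exact confidence
    intervals, association tests, ROC analysis with DeLong intervals),
    encodes the intraoperative perfusion decision protocol and the stepwise
    StO2 prediction algorithm, performs Spearman correlation network
    analysis, and generates fully seeded synthetic cohorts, bolus curves and
    frame stacks emulating the structure of a 68-patient, 340-point
    laparoscopic colorectal surgery study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    pROC,
    igraph,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
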