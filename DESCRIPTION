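Package: cytobin
Title: Gating-Free Discovery of Discriminating Cell Sub-Regions in Cytometry
    Data by Equal-Frequency Binning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Coarse-grains every two-dimensional marker-pair scatter plot of
    single-cell cytometry data into equal-frequency percentile boxes, selects
    the marker pairs whose box-percentage profiles perfectly discriminate two
    sample groups with a linear support-vector classifier, and pinpoints the
    boxes (cell sub-regions) that differ significantly between groups by
    exact Mann-Whitney tests with Bonferroni correction.  A random-relabeling
    calibration estimates the false positive rate of perfect classification
    as a function of the number of bins, guarding against overfitting when
    cohorts are small.  Includes readers for FCS 3.x list-mode files and
    delimited text matrices, spillover compensation, the biexponential
    logicle transformation, and a synthetic point-pattern cohort generator
    for calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: FlowCytometry, SingleCell, Classification, ImmunoOncology
RoxygenNote: 7.3.3
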