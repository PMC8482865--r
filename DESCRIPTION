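Package: vipquant
Title: Quantification Pipelines for VIP Interneuron Synaptic Imaging and
    Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tested implementations of the image-analysis and
    electrophysiology quantification procedures used to characterise
    synaptic properties of cortical VIP interneuron subtypes: 3D
    colocalization of presynaptic mGluR7 immunopuncta with labelled
    neurite processes after soma removal (blob enhancement, Otsu
    thresholding, active-contour refinement, 3D connected components,
    volume normalisation), per-cell multiplexed fluorescent in situ
    hybridisation quantification with a prior-matched calretinin
    classifier, paired-pulse ratio measurement of evoked synaptic
    currents with summation correction, and the accompanying group
    statistics (exact Mann-Whitney U, Welch and paired t tests, one-way
    ANOVA with Bonferroni post hoc, differential-expression candidate
    filtering). A synthetic-data module generates ground-truthed image
    stacks, ISH images and sweep sets with the statistical structure
    each pipeline stage assumes, so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
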