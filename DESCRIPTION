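Package: protonSelect
Title: Model-Based Photon/Proton Treatment Selection with NTCP Decision Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for model-based selection between photon (VMAT) and proton
    (IMPT) radiotherapy in head-and-neck cancer. Reduces 3D dose grids and
    binary structure masks to organ-at-risk mean doses and dose-volume
    histogram statistics, evaluates the four Dutch NIPP logistic NTCP models
    for grade >=2 and grade >=3 xerostomia and dysphagia, applies the NIPP
    delta-NTCP decision tree with auditable rule traces, and quantifies
    decision performance (accuracy, sensitivity, specificity, F-score, AUC,
    paired t-tests). A parametric head-and-neck dose-phantom generator with an
    analytic distance-to-target dose falloff surrogate provides paired
    photon/proton cohorts so the full pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
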