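Package: dosiomics
Title: Dosimetric Radiomics and NTCP Modelling for 3D Radiotherapy Dose
    Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing 3D radiotherapy dose distributions inside
    organ-at-risk masks. Extracts a fixed panel of 91 IBSI-style dosimetric
    radiomic features (intensity, intensity histogram, GLCM, GLRLM, GLSZM,
    NGTDM) from dose grids discretized at a fixed bin width, computes
    dose-volume histogram metrics (Vx, Dx, D1cc/D2cc) with EQD2
    linear-quadratic conversion and hotspot-aligned summation of external
    beam and brachytherapy DVHs, and builds logistic normal tissue
    complication probability (NTCP) models via univariate screening,
    Spearman redundancy filtering and backward elimination, evaluated with
    ROC AUC, Youden cutoffs and balanced accuracy. Includes a synthetic
    cohort generator with planted outcome models so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
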