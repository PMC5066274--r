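Package: qsmcoloc
Title: Brain Iron and Amyloid Colocalization from Multi-Modal 7T Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline linking brain iron, measured by
    quantitative susceptibility mapping (QSM) of multi-echo gradient-echo
    phase, with amyloid plaque load measured by PiB-PET SUVR, inside brain
    regions defined by an iron- and MCI-dependent resting-state
    connectivity contrast. Implements Laplacian phase unwrapping, V-SHARP
    background-field removal, LSQR dipole inversion, SUVR quantification,
    seed-based connectivity with an FDR-thresholded group mask, ROI group
    statistics (ANCOVA, Cohen's d, median splits, odds ratios) and the
    susceptibility-SUVR colocalization analysis. A fully synthetic
    multi-modal cohort generator makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    digest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
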