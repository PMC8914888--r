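Package: dentateqsm
Title: Quantitative Susceptibility Mapping and Morphometry of the Cerebellar Dentate Nuclei
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for quantitative susceptibility
    mapping (QSM) of the cerebellar dentate nuclei. Provides a synthetic
    multi-echo gradient-echo phantom and cohort generator built on the forward
    dipole model; susceptibility-map reconstruction (3D quality-guided phase
    unwrapping, multi-echo frequency combination, multi-radius SHARP background
    field removal, thresholded k-space dipole inversion, brain-referencing) and
    R2* mapping; dentate volume-of-interest construction from silhouette
    tracings via per-hemisphere convex hulls with CSF exclusion; and the
    statistical layer used in dentate morphometry studies: head-size
    residualization, ANCOVA with partial eta squared, Sidak-adjusted post hocs,
    age-controlled rank correlations, intraclass correlation, and voxelwise
    permutation tests with threshold-free cluster enhancement and family-wise
    error control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
NeedsCompilation: yes
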