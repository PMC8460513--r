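Package: fetalmorph
Title: Fetal Brain Cortical Surface Morphometry and Longitudinal Spectral Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric analysis of segmented fetal brain MRI: structure
    volumetry from labeled volumes, surface extraction and area, a global
    shape parameter (surface area over volume), per-vertex principal
    curvatures with curvedness and shape index, longitudinal vertex
    correspondence of cortical surfaces by rigid coherent point drift
    initialisation followed by joint spectral matching with post-to-pre
    scalar field transfer, lobe-wise surface parcellation by label transfer,
    landmark-based posterior fossa biometry (transverse cerebellar diameter,
    ventricular width, cerebellar herniation level, clivus-supraocciput
    angle), and nonparametric group statistics (Anderson-Darling normality
    screen, Kruskal-Wallis tests with exact small-sample permutation option,
    median/IQR summaries, Pearson correlations with strength labels).
    Includes a synthetic gyrified brain phantom generator with analytic
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    RNifti,
    nortest,
    pracma,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
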