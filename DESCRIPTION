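Package: metaconn
Title: Metabolic Connectivity and Multimodal Group Analysis for Dementia Neuroimaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise group analysis of FDG-PET standardized uptake value
    ratio (SUVr) and gray-matter maps, seed-based interregional metabolic
    covariance analysis with goodness-of-fit scoring against functional
    network templates, voxelwise connectivity interaction contrasts,
    network-ratio and region-of-interest features with pairwise ROC
    discrimination, and tabular comparisons of subcortical volumes (linear
    models, Bonferroni) and regional white-matter-hyperintensity volumes
    (gamma GLM, log link). Includes a deterministic synthetic-cohort
    generator with latent-network covariance structure so the full pipeline
    can be exercised and calibrated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    pROC,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
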