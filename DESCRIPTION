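Package: octaperf
Title: OCT Angiography Perfusion Density and Foveal Avascular Zone Quantification
Version: 0.1.0
Authors@R: person("octaperf", "developers", role = c("aut", "cre"),
    email = "octaperf@example.org")
Description: Quantification pipeline for en-face optical coherence tomography
    angiography (OCT-A). Derives the axial slab boundaries of the superficial
    and deep capillary plexuses and the choriocapillaris from ILM/RPE surface
    maps, binarizes en-face angiograms with a global mean threshold, excludes a
    polygon-delineated foveal avascular zone (FAZ), and computes FAZ-subtracted
    perfusion density per plexus. Includes exact nonparametric cohort statistics
    (Wilcoxon signed rank, Mann-Whitney, Spearman), noncentral-t power
    arithmetic, a synthetic OCT-A generator with known ground truth for paired
    longitudinal cohorts, and a command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    jpeg,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
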