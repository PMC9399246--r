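Package: anoscore
Title: GAN-Based Anomaly Scoring of Breast Reconstruction Cosmesis from CT Surface Renders
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies cosmetic abnormality of reconstructed breasts from frontal
    surface renders of chest CT. A Wasserstein GAN with gradient penalty is trained
    on normal-breast renders, an encoder maps images to the latent space (izi_f
    scheme), and each image receives an anomaly score combining reconstruction
    error and critic-feature dissimilarity, standardized as a z-score against the
    normal reference set. Longitudinal score trajectories across pre-radiotherapy
    and one- and two-year follow-up visits are analyzed with paired t-tests,
    trajectory-pattern classification, and a random-intercept linear mixed model
    with time-interaction contrasts. Includes seeded generators for synthetic
    torso phantoms (volumes and depth renders) and for simulated longitudinal
    cohorts, plus a parameter-recovery experiment for the mixed model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python with pydicom (only for DICOM series import)
Config/testthat/edition: 3
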