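Package: gliomafc
Title: Tumor-to-Network Resting-State Functional Connectivity in
    Amino-Acid-PET-Defined Glioma Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies resting-state functional connectivity (FC) between
    a metabolically active tumor region, segmented on amino acid PET as a
    tumor-to-brain ratio (TBR) of 1.6 or more, and the seven canonical
    resting-state networks, using a lesion-cropped atlas-seed regression
    with Fisher z-scored connectivity maps.  Relates per-subject FC
    profiles to overall survival via Kaplan-Meier, log-rank and Cox
    proportional-hazards models including stepwise covariate selection,
    and provides mixed repeated-measures ANOVA with Greenhouse-Geisser
    correction for network-level comparisons.  A fully synthetic cohort
    generator produces co-registered BOLD, PET, lesion-mask and survival
    data with planted ground truth so that every pipeline stage is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    RNifti,
    signal,
    survival,
    car,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
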