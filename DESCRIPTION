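Package: fibroscore
Title: Quantitative Image Features and a Lasso Fibrosis Score for
    Scleroderma Skin Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic-testable pipeline for
    quantifying systemic sclerosis (SSc) skin disease from trichrome-stained
    biopsy sections. Samples random dermal image patches from calibrated
    section images, converts each patch into a vector of quantitative image
    features (a deterministic stain/texture backend or a seeded
    convolutional backend), fits a patch-level lasso regression of the
    modified Rodnan skin score (mRSS) on the features with
    leave-patients-out cross-validation, and averages patch predictions
    into a per-biopsy Fibrosis Score. Also implements the accompanying
    histopathology statistics: Cohen's kappa rater agreement with the
    standard agreement bands, proportional-odds ordinal regression odds
    ratios, random-intercept-and-slope mixed models for per-week change,
    and Spearman rank correlation. A synthetic-data module generates
    trichrome-like slides with planted severity, longitudinal cohorts in
    the diffuse-cutaneous eligibility band, two-rater score sheets with
    controllable agreement, and proportional-odds ordinal outcomes, so the
    whole pipeline is testable without any patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    glmnet,
    lme4,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
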