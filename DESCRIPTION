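Package: psvcc
Title: Choriocapillaris Flow-Deficit Quantification at Perforating Scleral
    Vessel Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies choriocapillaris (CC) flow deficits from en-face
    swept-source OCTA slabs at the choroidal entry sites of perforating
    scleral vessels (PSVs). Implements inverse-structure signal
    compensation, Phansalkar local adaptive thresholding, large-retinal-
    vessel exclusion masking, region-of-interest and concentric-ring flow
    deficit metrics (FDPSV, FD250), grid-based vessel-to-fovea distance,
    and Bennett-Littmann axial-length magnification correction. Includes
    a synthetic scene and cohort generator with known ground truth, and a
    statistical stage with Spearman screens, nested-random-intercept
    linear mixed-effects models, variance inflation factors, intraclass
    correlation repeatability, and noncentral-t post hoc power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    lme4,
    png,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
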