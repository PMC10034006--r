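Package: tgflsci
Title: Laser Speckle Contrast Imaging Analysis of Tubuloglomerular Feedback Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for renal cortical blood-flow recordings made with
    high-resolution laser speckle contrast imaging: fiducial-based frame
    registration, temporal speckle contrast (K = sd/mean over 25-frame kernels)
    and blood-flow-index (BFI = 1/K^2) conversion at 1 Hz, star-vessel
    segmentation, superlet time-frequency spectra of per-vessel flow series,
    three tubuloglomerular-feedback (TGF) oscillation metrics (mean BFI, Sigma
    of the 0.015-0.04 Hz band-filtered signal, baseline-corrected band AUC of
    the power spectrum), and linear mixed-effects comparison of control versus
    drug periods. Includes a synthetic-data module generating dynamic speckle
    stacks, star-vessel flow maps, and multi-animal cohorts with furosemide and
    phlorizin effect presets, each paired with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    jsonlite,
    lattice,
    lme4,
    lmerTest,
    pracma,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
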