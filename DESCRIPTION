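Package: tfquant
Title: Quantitative Single-Cell Imaging of Transcription-Factor Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Moment-based Number & Brightness analysis of fluorescence
    fluctuation image stacks (detrending, apparent-brightness maps, monomer
    calibration and oligomer-cursor classification), single-molecule tracking
    analysis (spot detection, gap-aware trajectory linking, MSD diffusion
    estimation, confined/non-confined mobility classification, and
    interval-censored two-exponential residence-time fitting), and
    texture-based population phenotyping of nuclei (Haralick feature
    extraction, z-scoring, condensation into population centers, PCA + SVM
    confusion matrices, distance matrices and bootstrap optimization of the
    condensation number). Ships simulators with known ground truth for every
    analysis so each stage is verifiable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    withr,
    jsonlite,
    tiff,
    e1071,
    mclust,
    survival,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
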