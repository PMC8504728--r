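Package: pelvimetrics
Title: Landmark Pelvimetry, CT Gut Volumetry, and Sex-Specific
    Allometric Regression of the Pelvic Canal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how gut size relates to the bony pelvic
    canal. Computes obstetric canal dimensions (inlet, midplane, outlet),
    shape indices and two angular statistics of the ischial-spine/S5
    triangle from 11 named 3D landmarks; estimates gut volume from binary
    intestinal mask stacks by slice-area summation; quantifies observer
    agreement with the two-way absolute-agreement intraclass correlation
    and a fuzzy-landmark replicate-averaging rule; and fits sex-specific
    log-log regressions of canal measures on gut volume and body weight
    with a relative-weights decomposition of R-squared. A synthetic-data
    generator emulates the statistical structure of a CT cohort so every
    stage has a parameter-recovery test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
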