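Package: nodulr
Title: Simulated Fluorescence Imaging and Sanctions Analysis for Legume Root Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates two-channel fluorescent root-mosaic images of pea root
    systems inoculated with reciprocally labeled nitrogen-fixing (Fix+) and
    non-fixing (Fix-) rhizobia, with known ground truth; detects and classifies
    nodules (single-infection, mixed-infection, non-fluorescent) from the
    images; quantifies per-strain nodule occupancy; computes among-nodule and
    within-nodule sanctions strictness; and tests occupant contrasts and the
    strictness-virus-titer association with cluster-aware permutation
    procedures. Designed for end-to-end parameter-recovery studies of host
    sanctions in the legume-rhizobium mutualism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml,
    EBImage
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
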