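Package: satb2quant
Title: Quantification of Cell-Based Functional Assays for SATB2 Missense Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for the cell-based assays used to
    functionally classify missense variants of nuclear matrix-attachment-region
    binding transcription factors such as SATB2. Implements the four automatic
    8-bit histogram thresholds used in ImageJ-style image quantification
    (Otsu, Li, Moments, Minimum), thresholded-area nuclear localization and
    colocalization ratios with intensity line profiles, FRAP (fluorescence
    recovery after photobleaching) curve normalization and single-exponential
    half-time fitting, dual-luciferase relative-activity computation, one-way
    ANOVA with Dunnett many-to-one post hoc comparisons, and a rule-based
    classifier that combines the standardized readouts into functional
    subgroups (partial loss-of-function, increased function, condensate-forming).
    Ships seeded synthetic-data generators for two-channel nuclear micrographs,
    FRAP recordings, and luciferase plates so every stage has a ground-truth
    test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
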