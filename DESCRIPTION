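Package: manipusel
Title: Host-Manipulation Assays, Truncation Selection and Repeatability for
    Copepod Behaviour Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for experimental-evolution studies of parasite
    host manipulation in copepods. Tracks a single animal through grayscale
    drop-plate image sequences (blob detection, movement-threshold activity
    scoring), computes the per-host manipulation statistic (post-infectivity
    minus pre-infectivity mean activity), implements truncation selection with
    replicate-faithful line assignment and selection differentials, and
    estimates behavioural repeatability and nested-model likelihood-ratio
    comparisons from linear mixed models. A synthetic-data module generates
    ground-truth trajectories, rendered frames and multi-generation cohorts so
    the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    lme4,
    EBImage,
    png,
    yaml,
    jsonlite,
    withr,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
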