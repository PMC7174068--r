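Package: panelTMB
Title: Tumor Mutation Burden from Gene Panels Versus Whole Exome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes tumor mutation burden (TMB) from somatic variant
    lists under configurable variant-inclusion policies and coding
    footprints, compares TMB between targeted gene panels and whole-exome
    sequencing (Deming regression, Pearson correlation, Bland-Altman
    agreement), and relates TMB quartiles to overall survival with
    Kaplan-Meier curves and Cox proportional-hazards models. Includes a
    synthetic-cohort simulator (gene models, panels, per-sample annotated
    VCFs, clinical tables) so the full analysis is reproducible without
    access to controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings,
    vcfR,
    survival,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
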