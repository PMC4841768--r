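Package: ptmpipe
Title: PTM Stoichiometry, AP-MS Interactome Scoring and ChIP Signal Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy pipelines for quantifying post-translational-modification
    (PTM) proteoform stoichiometry from MS1 extracted ion chromatograms,
    scoring affinity-purification mass-spectrometry (AP-MS) interactomes
    from label-free quantitation ratios (bait-specificity and differential
    z-score calls), building normalized input-subtracted ChIP-seq tag
    density tracks with peak overlap and motif-fraction analysis, and
    simple expression filters (fold-change plus paired t-test, delta-Cq
    relative quantitation). Includes seeded synthetic-data generators with
    known ground truth for every stage.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
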