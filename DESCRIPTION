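Package: crmscreen
Title: Multi-Evidence Screening and Validation Analytics for Cis-Regulatory Modules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for prioritizing candidate cis-regulatory
    modules (enhancers) around a developmental gene locus from multiple lines
    of evidence: cross-species conservation calling from pairwise alignments,
    position-weight-matrix motif scanning with exact score p-values,
    chromatin-mark evidence scoring with a repressive-mark veto, insulation
    score TAD calling from contact matrices with CTCF boundary concordance
    and ATAC accessibility annotation, restriction-site binding-site
    disruption design, reporter-assay normalization with Dunnett many-to-one
    comparisons, and single-cell marker co-expression summaries. Ships
    seed-deterministic synthetic-locus generators with planted ground truth
    so every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    multcomp,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
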