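Package: editomer
Title: Construction of High-Confidence A-to-I RNA Editomes from
    Multi-Caller Candidate Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrates per-sample, per-method candidate A-to-I RNA editing
    site calls (read as A-to-G changes) into a high-confidence editome.
    Implements sequence-variant, repeat and mappability filtering of
    candidate sites, cross-sample cross-method consensus building with
    editing-level and reproducibility thresholds, strand-aware genomic
    context classification, database-annotation matching, and the decision
    rules that admit sites into the final compendium.  Ships the
    accompanying statistics (population-weighted Sanger validation ratios,
    minimal false-positive estimates, genomic-element enrichment odds
    ratios, and sequence-motif base-fraction profiles) and a deterministic
    synthetic-data generator that emulates multi-caller call sets over a
    toy annotated genome so every pipeline stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    graphics,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    SummarizedExperiment,
    VariantAnnotation,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
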