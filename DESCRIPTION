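Package: coldsmRNA
Title: Small RNA Sequencing Analysis of miRNA Responses to Cold Stress
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for plant small RNA sequencing studies of
    cold stress, built around paired control/treatment libraries from two
    sugarcane cultivars. Covers read cleaning and tag collapsing, hierarchical
    annotation of small RNA categories against non-coding RNA references,
    two-stage identification of known miRNAs on miRBase-style precursors,
    hairpin-based novel miRNA prediction with miRNA/miRNA* duplex criteria
    and a pluggable thermodynamic folding engine, reads-per-million
    normalization with replicate-free differential expression testing,
    plant-style miRNA target prediction, hypergeometric GO/KEGG enrichment,
    and relative quantification for RT-qPCR validation. Includes a seeded
    synthetic-data generator that plants hairpins, contaminants and known
    fold-change structure for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
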