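Package: mcetools
Title: Comparative Genomics of MCE-Domain Proteins
Version: 0.1.0
Authors@R:
    person("MCE", "Tools Developers", email = "mcetools@example.org",
           role = c("aut", "cre"))
Description: A tested, reusable pipeline for comparative-genomic analysis of
    bacterial MCE (Mammalian Cell Entry) domain proteins. Assigns ordered
    protein domain architectures from HMMER per-domain hit tables (with Pfam
    gathering-threshold filtering and same-clan overlap resolution), classifies
    proteins into the four canonical MCE architecture types (single MCE;
    MCE + DUF3407; three and seven tandem MCE domains), aggregates phylum-level
    prevalence over one randomly chosen representative genome per species,
    builds thresholded all-vs-all sequence-similarity networks with CD-HIT
    style greedy representative clustering and GraphML/SIF export, and extracts
    and clusters position-weighted gene neighbourhoods around MCE genes from
    GFF3 annotation. Ships a synthetic-data generator that plants ground-truth
    architectures, taxonomy, protein families and operon contexts so the whole
    pipeline is testable offline, plus a command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    igraph,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
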