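Package: rdscreen
Title: Repressive-Domain Discovery from Pooled Tiling Sort-Seq Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of pooled tiling effector-domain screens
    read out by FACS sorting (sort-seq). Designs frame-preserving 150-nt
    (50 amino acid) candidate tiling libraries over protein-coding
    sequences, deduplicates mapped fragments by unique molecular
    identifiers (UMIs), transforms fragment hits to protein-centric
    coverage, calls repressive domains (RDs) by per-position
    hypergeometric enrichment of the GFP-negative over the GFP-positive
    sorted fraction with Benjamini-Hochberg correction, reconciles
    replicates and reporter contexts, and annotates called domains with
    position-weight-matrix and short-linear-motif instances, motif
    clustering, domain/IDR overlap categories, and motif-versus-flank
    conservation statistics. A configurable synthetic-screen simulator
    with planted repressive intervals supports validation of the full
    pipeline without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
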