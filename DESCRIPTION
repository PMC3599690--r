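Package: cypminer
Title: Mining Cytochrome P450 Complements from Annotated Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies cytochrome P450 (CYP) candidates in annotated bacterial
    proteomes by the three P450 signature motifs (the I-helix oxygen-activation
    window, the K-helix EXXR salt bridge and the heme-binding GXXXCXG cysteine
    pocket), assigns family and subfamily by pairwise global-alignment identity
    thresholds (>40% family, >55% subfamily), builds neighbor-joining trees
    from identity distances, detects CYP gene neighborhoods with ferredoxins,
    ferredoxin reductases, ATP/GTP-binding proteins and transcriptional
    regulators, and computes per-gene sequence properties (G+C content,
    protein length, average molecular weight, isoelectric point). Includes a
    deterministic synthetic-genome generator with implanted motifs, controlled
    pairwise identities and planned gene neighborhoods for end-to-end
    validation without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    rtracklayer,
    ape,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    seqinr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
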