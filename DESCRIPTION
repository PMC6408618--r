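Package: supermat
Title: Construction of Partitioned Phylogenomic Supermatrices from
    Orthogroup Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assemble partitioned amino-acid supermatrices from
    per-orthogroup multiple sequence alignments, as used in transcriptome-based
    phylogenomics.  Implements per-site confidence masking from ZORRO-style
    score tracks, gene-occupancy threshold selection, evolutionary-rate
    trimming of orthogroups using mean percent pairwise identity as a rate
    proxy, Dayhoff six-state amino-acid recoding, and concatenation into
    supermatrices with RAxML/NEXUS partition files and occupancy and
    missing-data reports.  Includes a synthetic orthogroup-dataset simulator
    with known per-locus rates, per-taxon capture probabilities and injected
    low-confidence columns for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
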