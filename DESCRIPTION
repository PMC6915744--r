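Package: methsig
Title: Sequence-Context Signatures for Prioritizing Differential DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Builds per-CpG genomic signatures from conformational and
    cis-regulatory sequence features around differentially methylated sites
    (DMS) and ranks sites by a weighted-sum genomic index. Includes loading
    and differential filtering of beta-value matrices and bisulfite counts,
    extraction of fixed-offset sequence windows from a reference genome,
    detection of canonical G-quadruplex motifs, DNA palindromes,
    position-weight-matrix transcription-factor binding sites,
    Shapiro-Senapathy splice sites, annotation-track overlaps and
    pentamer-table DNA-shape changes induced by CpG methylation, plus
    group-level enrichment statistics and a seeded synthetic-data generator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
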