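Package: pseudoshadow
Title: Disambiguation and Functional Characterization of Transcribed Pseudogenes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for characterizing transcribed pseudogenes from short-read
    sequencing data. Implements a read-filtering step that re-attributes
    genome-mapped reads at pseudogene loci by comparing mismatch counts
    against coding cDNAs, union-exon FPKM quantification and transcribed-call
    thresholds, an identity-window diagnostic for residual parent-gene signal,
    Jensen-Shannon tissue-specificity scoring, pseudogene-parent expression
    correlation analyses, small-RNA density classification into
    parent-interactive and parent-independent producers, ChIP tag density and
    anchored meta-profile computation, and nucleotide diversity and
    conservation summaries. A synthetic-data module generates toy genomes,
    reads, tags, haplotypes and expression matrices with known ground truth so
    the whole pipeline can be exercised and validated at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    XVector,
    IRanges,
    GenomicRanges,
    S4Vectors,
    yaml,
    jsonlite,
    rlang
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
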