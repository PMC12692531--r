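Package: carpoligo
Title: Gene-Level 60-mer Microarray Design, QC and Two-Color Analysis Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and analysing gene-level oligonucleotide
    expression microarrays for species with heavily duplicated, isoform-rich
    transcriptomes (for example paleotetraploid cyprinid fish). Covers
    transcript ingestion from FASTA plus GFF3/GTF and collapsing to one
    representative transcript per gene; vector and low-complexity masking;
    3'-anchored 60-mer probe enumeration, composition scoring and selection
    with a full exclusion ledger; seed-and-extend cross-hybridization
    screening; randomized 8-subarray layout with embedded controls; spot-level
    signal-to-noise quality control and detection calls; two-color LOWESS dye
    normalization, 75th-percentile scaling and baseline-to-median centering;
    empirical-Bayes moderated-t contrasts with Benjamini-Hochberg control;
    qPCR standard-curve efficiency and platform concordance; enrichment-score
    and directional category reporting; and a synthetic transcriptome and
    scan simulator with recorded ground truth so every stage is testable
    offline.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
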