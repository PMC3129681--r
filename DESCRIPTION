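Package: asmappraise
Title: Quality Appraisal of De Novo Genome Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates de novo whole-genome assemblies against trusted
    reference material. Computes contiguity statistics (N50 and friends),
    base-level substitution/insertion/deletion rates and coverage against
    finished reference sequences, split-contig mis-assembly detection with
    length normalization, paired-end concordance classification, novel
    sequence discovery by chunked alignment with contamination screening,
    and gene representation metrics (transcript base coverage, cDNA
    completeness curves, gene fragmentation). Includes a seed-and-extend
    banded nucleotide aligner so the pipeline runs without external
    binaries, PSL interoperability for substituting external alignments,
    and a synthetic-data generator that plants defects with a machine
    readable truth ledger for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    BiocGenerics,
    GenomeInfoDb,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
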