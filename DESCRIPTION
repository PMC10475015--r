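Package: horseq
Title: Discovery and Annotation of Tandem Higher-Order Repeats in Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects large tandem repeat units and their higher-order repeat
    (HOR) organisation in genome assemblies. Maps a DNA sequence into a
    repeat-length spectrum using the complete K-string ensemble of
    inter-occurrence distances, detects spectral peaks corresponding to
    repeat-unit and HOR lengths, extracts repeat-unit copies, clusters them
    into monomer families by edit-distance divergence, builds per-family
    consensus sequences, scans assemblies base-by-base with each consensus on
    both strands, and assembles the resulting monomer hits into HOR copies and
    tandem arrays with count reports and aligned text schemes. Ships a
    synthetic-genome simulator that plants HOR arrays with known ground truth
    so every stage of the pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
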