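Package: synmir
Title: Synteny-Based Discovery of Orthologous Pre-miRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers annotated pre-miRNA loci from a reference genome to a
    target genome through UCSC chain alignments (liftover), collapses
    overlapping members of the same miRNA family, screens candidates with a
    transparent hairpin-structure filter (weighted base-pair maximisation,
    dinucleotide-preserving randomization test), cross-references predictions
    against known annotations via an overlap-ratio rule, classifies miRNA
    genes as intronic or intergenic, extracts their upstream regulatory
    sequences and scans them with JASPAR-style position frequency matrices.
    Includes a deterministic simulator that builds paired genomes with a
    ground-truth chain file, planted hairpins, gene models and planted motifs
    so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
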