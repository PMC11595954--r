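Package: mitomarker
Title: Mitochondrial Barcode-Marker Screening for Fungal Mitogenomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for screening mitochondrial core
    protein-coding genes as DNA barcode markers in fungal genera. Reads
    annotated mitogenomes from GenBank flat files, extracts core genes,
    builds per-gene and concatenated neighbor-joining phylogenies, scores
    candidate markers by topological concordance (Robinson-Foulds),
    interspecies diagnostic variation and length stability, reports
    clade-diagnostic SNP and InDel sites, and renders four-color DNA
    barcode images. Includes a sequence-evolution simulator with known
    ground truth so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    grDevices,
    png,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
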