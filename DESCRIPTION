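Package: cdkperturb
Title: Combinatorial CRISPR Interaction Scoring and Single-Cell
    Cell-Cycle Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for multimodal CRISPR/Cas9 perturbation
    experiments targeting cyclin-dependent kinases and related
    regulators. Implements dual-guide library combinatorics (pair
    enumeration, barcode design with Hamming-distance guarantees, oligo
    scaffold assembly, two-position alignment references), edit-distance
    guide-pair counting from paired reads, genetic-interaction scoring
    with single-guide fitness imputed from the full combinatorial table,
    a polar-coordinate single-cell cell-cycle embedding with circular
    statistics (two-sample Kuiper test) and cell-cycle signal removal,
    knockout transcriptome phenotyping (bootstrap median profiles, MDS,
    rank-sum differential expression), and a 5' exon-coverage-bias
    analysis for detecting premature transcription termination. All
    inputs can be generated by bundled simulators with planted ground
    truth for parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    mgcv,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
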