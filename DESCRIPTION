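Package: apascope
Title: Single-Cell Alternative Polyadenylation from 3'-Tag scRNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies poly(A) sites de novo from 3'-tag-based single-cell
    RNA-seq reads, quantifies per-cell poly(A)-site usage, scores
    cell-type-specific alternative polyadenylation by cross-validated
    neighbor voting on Hellinger-similarity cell networks, and classifies
    per-gene usage modality (distal, proximal, middle, bimodal, multimodal)
    by Jensen-Shannon divergence against reference distributions. Includes
    internal-priming artifact filtering, paraclu-style parametric density
    clustering for peak definition, and a deterministic simulator that
    generates genome, annotation, counts and reads with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
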