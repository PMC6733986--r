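Package: scStageNet
Title: Staging Single-Cell Keratinocyte Differentiation and Module-Level
    Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orders keratinocytes from single-cell RNA-seq into discrete
    differentiation stages by diffusion imputation and k-means-based
    approximate spectral clustering, screens a bulk cell-type atlas for
    keratinocyte-specific genes and transcription factors, computes
    moderated basal-versus-differentiated differential expression,
    compares length-scaled transcription-factor motif occurrence between
    state-specific super-enhancer sets, builds signed soft-thresholded
    module-level TF-to-gene regulatory networks, and scores candidate
    transcription factors for differentiation-promoting strength. A
    bundled synthetic-data generator with planted ground truth makes the
    whole pipeline testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    limma,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
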