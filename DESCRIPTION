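Package: scmosaic
Title: Mosaic Single-Cell Multi-Omics Integration via Contrastive Modality Alignment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates single-cell batches measured with different, partially
    overlapping sets of modalities (RNA, ATAC, protein/ADT, histone marks) into
    a common latent space. Modality alignment is learned with a contrastive
    objective that augments InfoNCE with intra-modality negatives to close the
    modality gap; modality-specific representations are trained independently
    and completed for missing modalities by cross-modality k-nearest-neighbor
    matching in the aligned space. Includes a synthetic mosaic-data generator
    with known ground truth, per-modality dimensionality reduction and batch
    correction, and an integration benchmarking stack (NMI, ARI, graph iLISI,
    FOSCTTM, matching score, min-max-scaled weighted aggregation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    rhdf5,
    optparse,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
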