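Package: pathfactor
Title: Pathway-Informed Latent Variable Factorization of Gene Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-phase penalized matrix factorization of a gene-by-sample
    expression matrix into non-negative gene loadings and sample scores,
    with latent variables aligned to a binary gene-set prior through
    per-latent-variable cross-validated sparse non-negative regression.
    Includes held-out annotation recovery scored by rank-sum AUC with
    Benjamini-Hochberg FDR, tissue-alignment t-statistic summaries, a
    transparent file-backed matrix format for out-of-core fitting, a
    seeded synthetic-data generator for end-to-end verification, and a
    command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    pracma,
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
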