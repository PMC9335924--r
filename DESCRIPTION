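Package: tdaign
Title: Weighted Tensor Decomposition with Auxiliary Similarity Networks for
    Multi-Type miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts multiple types of miRNA-disease associations by
    completing a sparse binary miRNA x disease x type tensor with a weighted
    CANDECOMP/PARAFAC decomposition regularized by multi-view biological
    similarity networks.  Provides the similarity constructions (MeSH-style
    disease semantic similarity, miRNA functional and sequence similarity,
    Gaussian interaction profile kernels), graph-Laplacian and L2,1-norm
    regularized factorization solved by alternating updates with ADMM and
    episode-wise positive-sample re-weighting, 5-fold cross-validation
    protocols over association types and triplets, ablation toggles, a
    seeded synthetic-data generator, and readers/writers for the plain-text
    interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
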