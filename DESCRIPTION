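Package: treecoda
Title: Phylogenetic Compositional Beta-Diversity via Masked Low-Rank Factorization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compositionally aware phylogenetic beta-diversity for sparse
    microbiome count tables. Expands a feature table to all internal nodes of a
    rooted phylogeny (the Fast UniFrac count array), applies a branch-length
    weighted robust centered log-ratio transform that treats zeros as missing,
    and factorizes the resulting masked matrix (phylo-RPCA) or subject-by-
    node-by-state tensor (phylo-CTF) to obtain ordinations, biplot loadings and
    sample distance matrices. Includes a data-driven three-block Poisson-
    lognormal simulator, a PERMANOVA/KNN evaluation harness, and node-
    aggregated log-ratio utilities with overlap protection and LCA taxonomy
    annotation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    biomformat,
    generics,
    ggplot2,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
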