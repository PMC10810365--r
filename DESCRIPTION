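Package: cycletsa
Title: Cross-Cell-Line Translation of CETSA Melting Curves via Cyclic
    Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting MS-CETSA protein melting profiles across
    cell lines with a cyclic multi-autoencoder: n encoders map each cell
    line's ten-temperature melting features into one shared latent space
    and n decoders map latent vectors back to any cell line, so a single
    set of 2n networks replaces the 2n(n-1) networks of pairwise
    translation.  Training combines a prediction loss over all ordered
    cell-line pairs, a cycle-consistency loss, and a latent-space
    regularisation loss.  The package includes wide-table I/O and panel
    alignment for CETSA melting data, a sigmoid melting-curve simulator
    with known ground truth, the full training loop (stochastic gradient
    descent with momentum, stepped learning-rate decay, early stopping,
    checkpointing), a five-metric transfer evaluation (MSE, MAPE, MAE,
    R-squared, Pearson correlation) over all ordered cell-line pairs, and
    a decision-tree regression harness that validates translated features
    by protein-protein interaction score prediction under k-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
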