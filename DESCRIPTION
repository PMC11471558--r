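Package: scMosaic
Title: Mosaic Integration of Trimodal Single-Cell Data with a
    Product-of-Experts Variational Autoencoder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Joint analysis of single-cell multimodal experiments in which
    different batches measured different, overlapping subsets of modalities
    (chromatin accessibility, transcriptome and surface proteins). The core
    is a modular variational autoencoder with a product-of-experts posterior
    over two disentangled latent variables, a biological state and a
    technical-noise component, trained with a self-supervised modality
    alignment penalty and adversarial information-bottleneck losses against
    batch classifiers. Downstream task heads cover latent-space integration,
    imputation of missing modalities and features, batch correction by
    technical-noise substitution, transfer learning onto query datasets,
    reciprocal reference mapping, and k-nearest-neighbour label transfer
    with novel-cell-type detection. A benchmarking suite implements graph
    iLISI/cLISI, graph connectivity, kBET, modality silhouette, FOSCTTM,
    label-transfer F1, cross-modal feature recovery and weighted overall
    scores, and a seeded synthetic-data generator produces trimodal mosaic
    datasets with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    cluster,
    igraph,
    jsonlite,
    pROC,
    yaml
Suggests:
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'featureSpace.R'
    'io.R'
    'nn.R'
    'network.R'
    'losses.R'
    'train.R'
    'tasks.R'
    'metrics.R'
    'transfer.R'
    'cli.R'
    'simulate.R'
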