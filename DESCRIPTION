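Package: mgembed
Title: Multi-Graph Gaussian Embedding of Weighted Functional Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes every node (region of interest) of multiple weighted
    functional brain connectivity networks as a low-dimensional multivariate
    Gaussian distribution, using a shared feed-forward encoder trained with a
    Kullback-Leibler ranking loss over weighted k-hop node triplets. Provides
    the surrounding analysis pipeline: Pearson connectivity construction from
    ROI time series, connectivity thresholding, edge hold-out link-prediction
    evaluation (AUC), Wasserstein-2 quantification of pre/post-intervention
    network change, a cross-subject reorganization index with one-sample
    t-tests and false-discovery-rate correction, uncertainty-based effective
    latent dimensionality, and a synthetic multi-subject connectome generator
    with planted community structure and intervention perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
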