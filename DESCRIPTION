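Package: vflsim
Title: Simulation of Vertical Federated Learning with Overcomplete Autoencoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Single-machine simulation of a vertical federated learning (VFL)
    protocol for clinical tabular data with a binary outcome. Each
    data-holding site trains an overcomplete autoencoder (code layer at least
    as wide as its input) with categorical embeddings on its vertical slice of
    a shared cohort, transmits the latent codes once to a simulated relay, and
    a central server trains a tabular neural-network classifier on the
    row-aligned concatenation of all sites' codes. The package benchmarks the
    latent-federated model against centralized and per-site baselines
    (accuracy and AUROC, with signed relative percent differences), generates
    mixed-type synthetic cohorts with a known label signal for testing, and
    quantifies how far the transmitted codes are perturbed away from the raw
    features (correlation, linear reconstruction, distribution divergence).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'autoencoder.R'
    'classifier.R'
    'dataset.R'
    'embeddings.R'
    'experiment.R'
    'federation.R'
    'metrics.R'
    'nn-internals.R'
    'privacy.R'
    'schema.R'
    'synthetic.R'
    'tabular-core.R'
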