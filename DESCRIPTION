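Package: kinoforge
Title: Interpretable Latent-Space Generative Design of Kinase-Family Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A modular, chemistry-first toolkit for family-targeted kinase
    ligand design at desk scale. Molecules are standardized and profiled with
    a fixed panel of 20 physicochemical and topological descriptors, embedded
    in a continuous latent space by a trainable character-level SMILES
    variational autoencoder, and scored by a random-forest Kinase Association
    Likelihood (KAL) classifier that estimates structural proximity to a
    target family's ligand chemotypes. Two generative strategies operate on
    the latent manifold: Gaussian-process Bayesian optimization of the KAL
    objective (Matern 5/2 surrogate, Expected Improvement maximized by
    multi-start L-BFGS-B) and cluster-guided local neighborhood remodeling
    (K-means centroids, controlled interpolation with isotropic noise,
    decode-and-filter generation). Diagnostics cover PCA and kernel-density
    maps of the latent manifold, per-family latent statistics, similarity and
    drug-likeness reports, and seeded synthetic molecule libraries for
    end-to-end testing. Descriptor and fingerprint computation is delegated
    to RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
SystemRequirements: Python (>= 3.9) with rdkit on the PATH as 'python'
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'utils.R'
    'AllGenerics.R'
    'AllClasses.R'
    'gp.R'
    'bo.R'
    'chemstore.R'
    'landscape.R'
    'kal.R'
    'vocab.R'
    'vae.R'
    'neighborhood.R'
    'synthkit.R'
    'campaign.R'
    'kinoforge-package.R'
    'rdkit.R'
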