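Package: indolegen
Title: De Novo Generation of Indole-Like Molecules and Prediction of
    Cytoprotective Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end workflow for proposing novel indole-like
    molecules and estimating their cytoprotective activity under
    oxidative stress. Augments a small seed set of SMILES by enumeration,
    translates structures to the SELFIES grammar, trains a seeded
    autoencoder over one-hot token matrices and samples novel structures
    from its latent space with Gaussian noise. Activity (% inhibition of
    free-radical-induced hemolysis) is modelled by QSAR regression over
    molecular descriptors with correlation-threshold feature selection,
    comparing decision tree, random forest, k-nearest neighbours,
    multiple linear regression and support vector regression. Candidates
    are filtered by a fragment-additive Bayesian synthesizability score
    with a minimum-over-seed-set threshold, and the resulting library is
    characterised by Tanimoto similarity and a t-SNE chemical-space
    embedding. Chemistry plumbing (canonicalization, kekulization,
    properties, path fingerprints) is delegated to Open Babel through
    ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    stats,
    utils,
    jsonlite,
    rpart,
    randomForest,
    caret,
    e1071
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
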