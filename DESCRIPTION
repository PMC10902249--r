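Package: mesohab
Title: Habitat Projection and Protected-Area Assessment for Southern Ocean Mesopelagic Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Presence-only ensemble habitat modelling for Southern Ocean mesopelagic
    fish under climate-change scenarios. Provides a synthetic circumpolar data
    generator with known niche ground truth, occurrence cleaning and 1-degree
    spatial rarefaction, a TSS-weighted ensemble of random forest, boosted-tree
    and maximum-entropy-style distribution models with cross-validated AUC/TSS
    evaluation and permutation variable importance, a latent-factor probit joint
    species distribution model (Gibbs sampler) for residual species associations
    with 99% HPD significance, equal-area habitat gain/loss/stability and
    centroid-shift analytics, and marine protected-area overlap reports, all
    orchestrated by a configuration-driven pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ranger,
    xgboost,
    glmnet,
    pracma,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
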