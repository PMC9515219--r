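Package: transgrad
Title: Transdiagnostic Cortical Effect Dimensions and Multiscale Gradient Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts a shared disease dimension from condition-wise cortical
    thickness effect-size maps on a cortical parcellation and contextualises it
    against connectome gradients, intracortical profile features
    (statistical moments and externopyramidization), and neurotransmitter
    density maps. Provides microstructural profile covariance and functional
    connectivity gradient estimation by diffusion map embedding, spin-test
    spatial permutation correlations with false discovery rate control,
    stratification by functional community and hierarchy labels, and nested
    cross-validated LASSO prediction of a target map from a multiscale feature
    panel. A synthetic-data module generates parcellations, spatially
    autocorrelated maps, effect matrices, depth profiles, connectivity and
    feature panels with planted, recoverable structure so that every stage of
    the workflow can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
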