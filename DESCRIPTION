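Package: dalernn
Title: Excitatory-Inhibitory Rate RNNs for Multisensory Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains ensembles of Dale-constrained excitatory/inhibitory rate
    recurrent neural networks on a multisensory rate-discrimination task and
    characterizes the behavioral strategy of each network. Provides the task
    generator (noisy step-current stimuli encoding pulse frequencies in one
    or two modalities), network initialization and simulation, training by
    backpropagation through time with a sign-constraint projection,
    psychometric and chronometric curve fitting with optional lapse
    parameters, rate-based and ROC-based single-unit selectivity
    classification, modulatory-current and lesion experiments, permutation
    tests with Holm-Bonferroni correction, PCA trajectory analysis, and
    GLM-HMM inference of latent behavioral states.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
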