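Package: lnlcascade
Title: Analytic Jacobians and Inverses for Cascaded Linear+Nonlinear Vision Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Feed-forward cascades of linear+nonlinear (L+NL) modules are the
    workhorse of models of the visual pathway.  This package implements such
    cascades together with the mathematics beyond the forward transform:
    analytic Jacobians with respect to the stimulus and to the model
    parameters, and analytic layer-by-layer inverses.  Supported
    nonlinearities are canonical divisive normalization (with Gaussian
    interaction kernels), the steady state of the Wilson-Cowan equations, and
    a two-gamma tone-mapping curve.  On top of the calculus the package
    provides perceptual distances and second-order metrics, sensitivity and
    multi-information-reduction analyses, MAximum Differentiation (MAD)
    stimulus synthesis, gradient-based model fitting against mean opinion
    scores, and model-based decoding of simulated neural responses with
    regression baselines, plus seeded generators for natural-like synthetic
    stimuli.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    generics,
    rlang,
    tibble,
    ggplot2,
    jsonlite,
    yaml,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
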