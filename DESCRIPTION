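Package: buqoct
Title: Bayesian Uncertainty Quantification by Optimization for CT Image Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hypothesis testing on compact structures observed in computed
    tomography (CT) reconstructions, aimed at distinguishing pulmonary
    embolism (PE)-like filling defects from reconstruction artifacts.
    Implements a parallel-beam CT forward model, sparsity-constrained MAP
    reconstruction by primal-dual proximal splitting, a conservative
    posterior credible region, a convex "structure-absent" set built from
    neighborhood intensity and gradient histograms, and the BUQO set-distance
    test with its structure-confidence statistic. Includes a synthetic
    thorax phantom generator with PE-like inserts and artifact scenarios,
    and a command-line driver for simulation, testing and parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
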