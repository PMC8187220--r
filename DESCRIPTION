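Package: krrpes
Title: Kernel Ridge Regression Potential Energy Surfaces and
    Nuclear-Ensemble Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building machine-learned potential energy surfaces
    of single molecules with kernel ridge regression.  Implements the RE
    (relative inverse-distance), Coulomb-matrix and inverse-distance
    molecular descriptors with analytic Jacobians, Gaussian, Laplacian,
    exponential and Matern kernels with analytic gradients, a normalized
    permutationally invariant kernel for molecules with equivalent nuclei,
    regularized kernel-matrix solvers, farthest-point and structure-based
    sampling, nested-grid hyperparameter selection, delta-learning and
    self-correction workflows, automatic learning curves with power-law
    fits, and the machine-learning nuclear-ensemble algorithm for
    absorption cross sections.  Ships a synthetic-data module (Morse,
    harmonic and permutation-symmetric surfaces, labeled nuclear
    ensembles) so every workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
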