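Package: kernelgxe
Title: Bayesian Multi-Environment Genomic Prediction with Linear and Gaussian Kernels
Version: 0.1.0
Authors@R: person("kernelgxe", "maintainers", email = "maintainers@kernelgxe.org",
    role = c("aut", "cre"))
Description: Bayesian genomic prediction for multi-environment plant-breeding
    trials with genotype-by-environment interaction. Implements the
    single-environment kernel regression (GBLUP and Gaussian kernels with
    marginal-likelihood bandwidth selection), the multi-environment model with
    Kronecker-structured genetic covariance UE (x) K between environments, and
    its extension with an extra non-marker genetic effect with covariance
    FE (x) I, all fitted by exact Gibbs samplers with inverse-Wishart and
    scaled inverse chi-squared priors and data augmentation for missing
    phenotype cells. Includes marker quality control, CV2 cross-validation for
    prediction ability, synthetic data generation with the models' exact
    covariance structure, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
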