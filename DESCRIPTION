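Package: resilayer
Title: Resilience Indicator Traits and Purebred-Crossbred Genetic
    Parameters from Longitudinal Egg-Production Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to derive resilience indicator traits (log-variance,
    skewness and lag-one autocorrelation of weekly egg-production
    deviations from the batch average) from raw egg-collection records of
    laying hens, and to estimate their genetic parameters with
    pedigree-based REML.  Implements univariate and bivariate animal and
    sire models with heterogeneous residual variances by cage size,
    purebred-crossbred genetic correlations, heritability on the
    individual and pooled-cage scales, and boundary-corrected
    likelihood-ratio tests.  A synthetic-data generator reproduces the
    paternal half-sib family structure, batch lay curves, perturbation
    events and irregular egg-collection schedules typical of layer
    breeding programs, at two fidelity levels: direct draws from the
    linear mixed models and a full longitudinal process simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
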