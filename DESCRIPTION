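Package: medtriplet
Title: Measurement-Error-Aware Mediation Analysis for QTL Triplets
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how measurement error distorts causal mediation
    analysis of genetic triplets (QTL genotype X, candidate mediator M, target
    trait Y). Provides a correlation-parameterized measurement-error model for
    the Causal, Independent, Reactive, and Complex mediation structures; its
    single-latent-factor reparameterization with a closed-form tetrad estimator
    and consistency diagnostics; Bayesian model selection over mediation DAGs
    with conjugate closed-form Gaussian marginal likelihoods (three-choice and
    expanded option sets) and the equivalent weakest-correlation decision rule;
    a simulation engine for large-scale classification-rate studies with
    Beta-distributed causal and error correlations, including a multistate
    haplotype-dosage genotype variant; and bootstrap diagnostics that map
    observed data correlations to the feasible causal and error parameter
    configurations of each assumed structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
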