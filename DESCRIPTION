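Package: trajmix
Title: Infinite-Mixture Relaxation Models for Microbial Count Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian nonparametric inference of time-dependent signatures of
    microbial taxa from 16S sequencing-count time series under known
    perturbations such as antibiotic pulses. Taxa are clustered by a Dirichlet
    process infinite mixture over prototype signatures, piecewise
    constant/exponential-relaxation trajectories on a log scale with
    reversible-jump dimensionality switches, observed through a negative
    binomial count model with read-depth and taxon offsets. Provides MCMC
    inference, signature-diversity scores, relaxation-time distributions,
    consensus signature groups with taxon enrichment, Bayesian D-optimal
    experimental design, and a matched synthetic-data generator for
    benchmarking recovery.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    deSolve,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
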