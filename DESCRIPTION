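Package: divselABC
Title: Divergent-Selection Simulation and Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Martyna", "Developer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time simulation of two haploid SNP populations
    diverging under locus-specific selection with recurrent
    migration-selection cycles, recombination, and sexual or asexual
    reproduction. Provides per-locus differentiation and haplotype
    homozygosity summary statistics (FST, signed FST, allele-frequency
    difference, EHH and XP-EHH), an empirical-quantile FST outlier scan,
    and approximate Bayesian computation (rejection sampling plus
    kernel-weighted local-linear regression adjustment) for jointly
    estimating which loci are under divergent selection and their
    selection coefficients. Includes a deterministic single-locus
    expectation model used to validate the stochastic simulator, and a
    scenario harness that evaluates estimator mean squared error,
    variance and squared bias across migration rates, reproduction
    modes and numbers of selected loci.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
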