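Package: kincoop
Title: Kin Selection and Cooperative Gene Content in Host-Associated
    Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A comparative-analysis toolkit for testing Hamilton's rule in
    host-associated microbial communities. Estimates strain-level genetic
    relatedness from per-host allele-frequency panels with an FST-like
    estimator, quantifies cooperative gene content (secretome size and five
    ontology-based cooperation classes, plus sporulation scores), fits
    Bayesian phylogenetic mixed models (Poisson counts and Gaussian
    relatedness) by Metropolis-within-Gibbs MCMC, and synthesizes effects
    across cooperation classes with random-effects meta-analysis, a joint
    Wald test, infinite-island equilibrium theory, and a direct/indirect
    path summary. Includes a Wright-Fisher island-model simulator and
    comparative-dataset generators with known ground truth for validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    metafor,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
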