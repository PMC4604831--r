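Package: quartetcoal
Title: Multispecies Coalescent Analysis of Four-Taxon Species Trees
    under Incomplete Lineage Sorting and Gene Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study species-tree inference in four closely related
    species with large effective population sizes and post-divergence gene
    flow. Provides a structured-coalescent simulator for
    isolation-with-migration demographies with per-branch effective sizes
    and infinite-sites mutation, windowed gene-tree discordance metrics
    (topology spectra, the genealogical sorting index, a topology diversity
    index), analytic multispecies-coalescent expectations and a rooted-triple
    pseudo-likelihood species-tree estimator, joint site-frequency-spectrum
    composite-likelihood demographic model comparison with Akaike weights,
    and approximate Bayesian computation model choice with partial
    least-squares summary reduction and regression-adjusted posteriors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    nnet,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
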