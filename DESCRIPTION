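Package: mscquant
Title: Quantitative Trait Evolution Under the Multispecies Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models quantitative traits whose underlying loci evolve along
    gene trees drawn from the multispecies coalescent, rather than along the
    species tree itself. Provides closed-form expectations for trait
    variances and covariances on a three-species phylogeny, a gene-tree and
    trait simulator with tunable levels of incomplete lineage sorting,
    maximum-likelihood estimation of the Brownian-motion rate and Pagel's
    lambda, a simulation-based phylogenetic ANOVA, and a threshold-trait
    pattern classifier, so that the consequences of genealogical discordance
    (hemiplasy and the deep-coalescence effect) for comparative methods can
    be quantified by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
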