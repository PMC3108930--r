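Package: domainRBF
Title: Prioritizing Protein Domains for Disease Phenotypes with Bayes Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Scores the association between candidate protein domains and
    human disease phenotypes by a Bayes factor from a conjugate Bayesian
    linear regression of a phenotype-similarity profile on a network-derived
    domain-proximity profile. Provides diffusion and shortest-path Gaussian
    kernels on a domain-domain interaction network, rank-based inverse-normal
    transformation of the response, leave-one-out cross-validation under
    random-control, linkage-interval and genome-wide protocols, three
    permutation-null robustness suites, gene-level aggregation of domain
    scores, a genome-wide association landscape, and a SNP-proximity
    permutation test for enrichment of reported susceptibility SNPs near
    top-ranked domains. A seeded synthetic-scenario generator produces
    networks, associations, similarities, loci and SNPs with tunable planted
    signal for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
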