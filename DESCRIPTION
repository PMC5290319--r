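Package: metaphylo
Title: Metastatic Seeding Phylogenies from Multi-Sample Tumour Sequencing
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reconstructs the seeding phylogeny of metastases from
    multi-sample variant read-count data. A Bayesian binomial error model
    with a spike-at-zero, purity-aware prior converts read counts into
    per-sample presence/absence posteriors; reliability-weighted mutation
    patterns form an evolutionary conflict graph whose exact weighted
    minimum vertex cover yields the maximal set of evolutionarily
    compatible patterns; a unique perfect-and-persistent phylogeny is
    derived together with predicted sequencing artifacts (false-positives,
    well- and under-powered false-negatives), bootstrap branch support and
    optional subclone separation for polyphyletic samples. A multi-type
    branching-process simulator of metastatic progression with in-silico
    sequencing, plus branching-error and mutation-matrix error metrics and
    a neighbour-joining baseline, support benchmarking against ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
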