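Package: ntdp
Title: Semi-Nonparametric Modeling and Prediction of Topological Domains
    from Histone Modification Data
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models the relationship between histone-modification densities
    and topologically associating domains (TADs) with a convex conditional
    model over genome bins. Per-mark effect functions are shape-constrained
    Bernstein polynomials; a linear-chain state structure (domain start,
    interior, domain end, inter-domain) yields an exact log-space partition
    function and forward-backward marginals. Training combines the convex
    negative log-likelihood with a group-lasso penalty (handled through a
    Cauchy-Schwarz surrogate and alternating optimization) and a closed-form
    curvature smoothness penalty; domains are then predicted from histone
    data alone by exact dynamic programming over the interval graph of
    candidate domains. Includes partition-comparison metrics (variation of
    information), a length-preserving domain shuffle null, BIC-driven mark
    subset selection, and a synthetic-corpus generator with the model's own
    statistical structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo: Rcpp
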