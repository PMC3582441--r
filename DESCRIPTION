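Package: haplomix
Title: Mixture-Model Single Individual Haplotyping with Confidence Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single individual haplotyping (haplotype assembly) from aligned
    SNP fragments using a two-component mixture model fitted by variational
    Bayes EM with a twist-restart heuristic. Provides a per-boundary
    connectivity score and the derived minimum-connectivity (MC) block
    confidence score for extracting reliably phased segments, a chimeric
    fragment detector for pooled long-fragment sequencing data, a
    pairwise-consistency evaluation suite (precision, recall, switch-error
    rate, majority-vote baseline), and a fragment simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
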