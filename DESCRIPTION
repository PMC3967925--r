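Package: mrfaln
Title: Protein Remote Homology Detection by Alignment of Markov Random Field Family Models
Version: 0.1.0
Authors@R:
    person("mrfaln", "developers", email = "mrfaln@example.org", role = c("aut", "cre"))
Description: Models a protein family's multiple sequence alignment as a
    Markov random field (MRF) whose nodes carry column amino-acid marginals
    and whose edges carry mutual-information interaction features.  Scores
    the similarity of two MRFs with a trained node alignment potential and a
    long-range edge alignment potential over binned inter-residue distances,
    and aligns two MRFs by an ADMM decomposition of the quadratic alignment
    objective into dynamic-programming subproblems.  Includes a Viterbi
    prefilter plus rerank search driver, reference-dependent alignment
    precision/recall evaluation, and a synthetic family-pair generator with
    planted contact scaffolds and a known true alignment for end-to-end
    benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    withr,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
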