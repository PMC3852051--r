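Package: coevomap
Title: Maximum-Likelihood Mapping of Paralogs Between Coevolving Protein Families
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps paralogous proteins between two putatively interacting
    protein families from their multiple sequence alignments. Pairs of mapped
    protein pairs ("units of coevolution") are scored by the hypergeometric
    probability of the observed mismatch split under equal evolutionary rates,
    and the maximum-likelihood species-constrained matching is found by a
    Lagrangian relaxation of the resulting binary quadratic program, with
    provable upper and lower bounds on the optimum. Includes a synthetic
    coevolving-family generator, exact enumeration for small instances,
    recall/precision evaluation, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
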