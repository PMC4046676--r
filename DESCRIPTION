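Package: pseudosanger
Title: Pseudo-Sanger Sequences from Nested Paired-End Short-Read Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Transforms nested paired-end short-read libraries with stepwise
    decreasing insert sizes into long, near error-free "pseudo-Sanger" reads.
    Read pairs from the largest-insert library act as anchors; supporting
    reads from the smaller libraries are located with a blocked spaced-seed
    index, assembled by a constrained local overlap-layout-consensus step
    that must start and end at the two anchor reads, and polished by a
    second consensus over all read pairs falling inside the primitive
    sequence. Includes a wgsim-style diploid read simulator with uniform
    substitution errors, a repeat gate based on the expected number of
    supporting reads per anchor, and an evaluation harness measuring
    residual error against simulated truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
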