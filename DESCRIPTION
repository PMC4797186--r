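Package: entroprof
Title: Multi-Resolution Alignment-Free Comparison of Regulatory Sequences
    with Entropic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Alignment-free similarity statistics for DNA regulatory
    sequences (enhancers, cis-regulatory modules) built on Entropic
    Profiles. Implements the multi-resolution statistics EP2 and EP2*,
    which replace fixed-length k-mer counts with Gaussian-weighted
    averages of variable-length suffix counts, together with exact
    expectations and variances of overlapping word counts under
    order-0 and order-1 Markov background models, the classical D2,
    D2S and D2* baselines, a pattern-transfer motif-implantation
    simulator, and the positive-predictive-value protocol used to
    benchmark discrimination of functionally related sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
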