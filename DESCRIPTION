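Package: tailbench
Title: Poly(A) Tail Length Inference and Benchmarking from Nanopore Raw Signal
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates direct-RNA nanopore raw current reads with known
    poly(A) tail lengths and realistic artifact processes (tail degradation,
    fragmentation, internal-site mispriming, split reads), locates the
    poly(A) region with three segmentation strategies (a linear-chain hidden
    Markov model decoded by Viterbi, a two-pass sliding-window method, and a
    conservative anchor-and-grow method), converts sample-space boundaries
    to nucleotide lengths via read-specific translocation rates, and
    benchmarks estimators with kernel-density "maxpeak" averaging,
    full-width-at-half-maximum peak widths, windowed mean absolute error
    with bootstrap confidence intervals and significance tests, and
    short-tail origin diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    optparse,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
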