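Package: blockshuffler
Title: Design, Simulation and Decoding of Overhang-Based Combinatorial
    DNA Block Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for combinatorial DNA libraries assembled by
    sticky-end ligation of short degenerate DNA blocks. Designs
    degenerate hexapeptide-coding blocks with non-palindromic
    dinucleotide overhangs for restricted amino-acid alphabets,
    stochastically simulates one-pot directional ligation with adapter
    capping and Illumina-style read generation, decodes sequenced
    libraries (quality trimming, N filtering, adapter-anchored insert
    extraction, 18-bp block calling) with a four-way
    correct/nonsense/missense/wrong-length classification, and
    aggregates library statistics: length distributions, block
    co-occurrence, representation counts, occupancy-based diversity
    estimates and amino-acid frequency comparisons against poly-NNK.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
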