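Package: spikePID
Title: Transfer Entropy Effective Networks and Partial Information
    Decomposition for Spike Trains
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds directed effective-connectivity networks from
    multineuron spike-train recordings using delayed transfer entropy with
    jitter-surrogate significance testing, decomposes the multivariate
    transfer entropy of sender-pair/receiver triads into unique, redundant,
    and synergistic components (Williams-Beer I_min partial information
    decomposition), and relates synergy, redundancy, and information
    transmission to normalized sender mutual information across multiple
    analysis timescales via decile-based regime statistics. Includes a
    correlated-Poisson spike-train simulator with known ground truth for
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    withr,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
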