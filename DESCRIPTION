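Package: operand
Title: Optimal-Embedding Transition Detection for Scalar Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects approaching transition points in scalar time series by
    comparing nonlinear dimensionality estimates between windows immediately
    preceding transition onsets and reference windows far from any onset.
    Dimensionality is estimated two ways: the optimal time-delay embedding
    dimension via the false-nearest-neighbour criterion, and the transitivity
    dimension of the recurrence network built from a recurrence plot.
    Includes onset detection by a first-difference threshold, sliding-window
    bookkeeping, Wilcoxon rank-sum comparison of the two window sets, a
    text-to-emotional-polarity front end based on semantic orientation
    against paradigm word sets, and seeded synthetic generators (Lorenz,
    Henon, noisy sine, AR(1), toy corpora) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
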