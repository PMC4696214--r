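Package: popchain
Title: State-Rich Markov Chain Tools for Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and analyses the dense, column-stochastic transition
    matrices of genotype-frequency Wright-Fisher models with partial
    clonality and symmetric mutation.  Provides a structure-preserving
    sparse approximation algorithm that keeps column-stochasticity,
    irreducibility and aperiodicity while discarding near-zero transition
    probabilities; limiting distributions (dominant eigenvector) and
    expected first-passage times; network-analytic summaries (most
    probable neighbours and paths, flow thresholds, betweenness on
    negative-log weights); de Finetti ternary coordinates, heat-map
    transforms and landscape elevations; inbreeding-coefficient (F_IS)
    limiting distributions with divergence statistics and a G-test; and
    Morris elementary-effects screening of approximation quality over
    population size, mutation rate, clonality rate and threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite
Config/testthat/edition: 3
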