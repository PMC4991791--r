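Package: recruitnet
Title: Recruitment Networks and Directed Triangle Motifs in Recurrent Spiking Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates conductance-based leaky integrate-and-fire networks of
    excitatory and inhibitory neurons with lognormal synaptic weights, maps the
    resulting spiking into functional, active, and recruitment networks, and
    quantifies small-world structure and the four directed triangle motifs
    (fan-in, fan-out, middleman, cycle) against density-matched null models.
    Includes triplet-level spike-timing analyses at fan-in triangle and simple
    convergence motifs, voltage-conditioned presynaptic ensemble maps, a
    calcium-imaging arm (event detection from fluorescence traces, iterative
    lagged-coactivation inference of directed functional weights, bootstrap
    false-positive analysis, spatial statistics), and synthetic-data generators
    (rate-matched Poisson surrogates, ground-truth calcium recordings, toy
    graph fixtures) that make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    igraph,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
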