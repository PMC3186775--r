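Package: phylodecline
Title: Molecular Phylogenetic Signature of Clades in Decline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for studying what declining diversity looks
    like in molecular (extant-only) phylogenies. Provides a two-phase
    birth-death tree simulator conditioned on final diversity and decline
    duration, deterministic tree operations (time slicing, reconstructed-tree
    pruning, random tip subsampling, internode-interval extraction), the
    gamma statistic of Pybus and Harvey with its star-phylogeny lower bound
    and size normalization, and replicated experiment drivers for the
    decline, under-sampling, pure-aging (stasis) and zero-speciation-decline
    scenarios, each tracing gamma and standing diversity back through time.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
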