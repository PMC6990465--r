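Package: topofilter
Title: Topological Filtering for Reduction and Selection of ODE Reaction
    Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Heuristic, sampling-coupled search over the lattice of
    submodels of a parametrized ordinary-differential-equation reaction
    network.  Model reductions are formulated as projections of
    multiplicative kinetic constants (and coupled parameters) to given
    projection values; a chi-squared goodness-of-fit threshold on the
    negative log-likelihood decides which parameter points, and thereby
    which submodels, are viable.  The package provides rank-bounded
    exhaustive testing of candidate reductions, per-sample union jumps,
    configurable enumeration strategies, experimental backtracking,
    adaptive re-sampling of the viable parameter subspace, parallel
    execution strategies, readers and writers for a declarative model
    format with optional SBML import, self-contained analytic fixtures,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    parallel,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
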