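Package: neuromaxent
Title: Maximum-Entropy Models of Neural Connectomes and Contactomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits canonical maximum-entropy ensembles of neural connectomes
    that combine topological constraints (degree sequence, edge count, total
    wiring length) with spatial and physical constraints (binned distance
    dependence, physical-contact networks). Provides a single modelling
    interface returning fitted ensemble objects with prediction, simulation
    and likelihood methods; tools to build contactomes from per-neuron point
    clouds; spatial statistics (exponential decay scales, soma-size
    estimation, finite-size cutoffs, directional decay); an evaluation suite
    (graphlet counts, network measures, wiring-length permutation tests,
    ROC/PR edge classification, synaptic-weight correlations, ensemble
    z-score comparisons); and seeded generators of planted multilayer
    connectome/contactome scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma,
    pROC,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
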