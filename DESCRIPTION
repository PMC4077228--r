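Package: seednet
Title: Integrated Disease-Gene and Drug-Target Interaction Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds protein-protein interaction networks anchored on two seed
    sets (disease-associated proteins and primary drug targets), restricted to
    the seeds and their one-step interaction neighbours. Computes network
    topology statistics (components, diameter, radius, characteristic path
    length, density, centralization, heterogeneity, clustering), extracts
    mediator proteins as the intersection of the two seed neighbourhoods,
    performs hypergeometric over-representation tests of annotation terms with
    a similarity-based term graph over the significant terms, and overlays
    mediators onto a reference interaction network with degree ranking and
    articulation-point analysis. Includes a seeded synthetic-interactome
    generator with planted ground truth so the whole pipeline can be exercised
    and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
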