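Package: phylocomm
Title: Phylogenetic Structure and Turnover of Plant Communities Along
    Environmental and Geographic Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Community phylogenetics toolkit for plot-based vegetation
    surveys along elevation and geographic gradients.  Computes mean
    pairwise (MPD) and mean nearest taxon (MNTD) phylogenetic distances
    with standardized effect sizes under a richness-preserving
    pool-randomization null model, phylogenetic beta diversity (Dpw, Dnn)
    with standardized effect sizes, habitat delimitation by multivariate
    regression trees selected by minimum cross-validated relative error,
    Dufrene-Legendre indicator species analysis with permutation tests,
    and Mantel / partial Mantel partitioning of environmental versus
    spatial distance effects.  Includes a synthetic-community generator
    with known assembly processes (neutral, environmental filtering,
    limiting similarity, dispersal limitation) so every stage of the
    pipeline can be validated against communities whose generating
    process is known.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    ape,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    vegan,
    rpart,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
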