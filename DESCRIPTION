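Package: commstruct
Title: Phylogenetic and Functional Structure of Communities Along
    Environmental Gradients
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the phylogenetic and functional structure
    of ecological communities sampled along an environmental gradient.
    Implements abundance-weighted mean pairwise and nearest-taxon distances
    with richness-preserving null models and standardized effect sizes,
    abundance-weighted phylogenetic and functional beta diversity (Dpw and
    Dnn) with tip-shuffle nulls, phylogenetic signal tests (randomization
    of independent-contrast variance and Blomberg's K), Gower trait
    dissimilarities, derivation of seasonal temperature predictors from
    monthly series, NMDS ordination with environmental vector fitting, and
    Mantel and partial Mantel tests. A synthetic-data generator produces
    phylogenies, traits with tunable signal, gradient-structured
    communities assembled under habitat filtering, neutral sampling or
    limiting similarity, and monthly temperature series, so the full
    pipeline can be exercised end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    stats,
    utils,
    tools,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    phytools,
    cluster
Config/testthat/edition: 3
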