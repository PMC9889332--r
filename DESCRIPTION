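Package: divfacets
Title: Taxonomic, Functional and Phylogenetic Diversity Across Habitat-Structured Communities
Version: 0.1.0
Authors@R:
    person("divfacets", "developers", email = "divfacets@example.org", role = c("aut", "cre"))
Description: Tools for comparing the three facets of community diversity --
    taxonomic (species richness), functional (convex-hull richness in a
    Gower/NMDS trait space), and phylogenetic (Faith's PD) -- at alpha, beta
    (pairwise Sorensen dissimilarity) and gamma (pooled, with subsampled
    site combinations) scales between habitat classes, together with
    sample-based rarefaction, continental grid-cell weighted-endemism
    complementarity, and a synthetic-data generator emulating biotic
    homogenization of habitat-structured amphibian communities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    withr
Config/testthat/edition: 3
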