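Package: sbgevol
Title: Evolution of Sex-Biased Gene Expression Across a Dioecious Plant Genus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of sex-biased gene expression (SBGE) evolution
    across a phylogeny of dioecious species. Calls sex-biased genes from
    replicated male/female RNA-seq counts per species (TMM normalization,
    exact negative-binomial tests, FDR plus fold-change thresholds),
    reconstructs the history of sex bias on the species tree with a
    three-state Mk model, quantifies rates of expression evolution by
    phylogenetically independent contrasts and by expression-distance versus
    sequence-divergence regressions with noise-matched permutation nulls, and
    classifies interspecific expression shifts as putatively adaptive with a
    divergence-over-polymorphism statistic (delta-x). Ships a synthetic-data
    generator emulating the study design (Brownian-motion expression evolution
    on a tree, species-specific injected sex bias, negative-binomial counts,
    fourfold-degenerate sequence divergence) so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    edgeR,
    vegan,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
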