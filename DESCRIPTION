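Package: chronosym
Title: Phylogenetic-Scale Decomposition of Host-Microbiome Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dissects host-associated microbiome variation across bacterial
    phylogenetic scales. Implements beta-diversity through time (BDTT):
    slicing a bacterial phylogeny at successive depths, collapsing sequence
    tables into slice-clade OTUs and profiling Sorensen, Bray-Curtis or
    UniFrac turnover against host phylogenetic and dietary distances with
    Mantel/MRM permutation inference and variance partitioning. Provides a
    two-state gain/loss CTMC with discrete-gamma rate variation for
    probabilistic ancestral community reconstruction, clade-wise
    phylosymbiosis standard effect sizes against independent-swap nulls,
    microbiome-based ancestral diet inference (ordination plus multinomial
    regression with AIC axis selection), and a synthetic-data generator that
    emulates diet-filtered deep bacterial clades and vertically inherited
    shallow clades for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    nnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
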