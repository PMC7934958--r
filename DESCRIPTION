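Package: immunevol
Title: Comparative Evolution of Immune Gene Repertoires on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of immune gene repertoire
    evolution across related species, built around three components: a
    conservative curation cascade that turns per-transcript annotation
    evidence (domain hits, homology hits, expression counts, taxonomy
    labels) from de novo transcriptome assemblies into a families-by-species
    gene count matrix; a phylogenetic-signal battery (Abouheif's C_mean,
    Moran's I, Blomberg's K and K*, Pagel's lambda) with permutation and
    likelihood-ratio tests; and a birth-death model of gene family size
    evolution with clade-specific rates, pruning likelihoods, maximum
    likelihood rate estimation, Monte Carlo family- and branch-level
    p-values, and ancestral family size reconstruction. A synthetic-data
    module generates every pipeline input with planted ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
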