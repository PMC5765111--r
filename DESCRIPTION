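Package: gbdphylo
Title: Genome BLAST Distance Phylogeny and Phylogenomic Character Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Distance-based phylogenomics for prokaryotic taxonomy:
    intergenomic distances computed from ungapped local-alignment hits
    between whole proteomes or genomes (the genome BLAST distance
    phylogeny, GBDP, approach), digital DNA-DNA hybridization estimates
    and genomic species delineation at the 70 percent threshold,
    neighbor-joining and balanced minimum evolution tree inference with
    pseudo-bootstrap support from hit resampling, a tip-permutation test
    of phylogenetic conservation for binary, ordinal and continuous
    characters scored by parsimony, congruence analysis of alternative
    trees via plain and bootstrap-weighted Robinson-Foulds distances with
    principal coordinates visualization, and chi-squared screening of
    associations between binary phenotypic features.  Includes a
    simulator (Yule trees, proteome evolution with substitutions and
    gene gain/loss, Mk/Brownian/noise characters) so every stage can be
    exercised against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    phangorn,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
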