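Package: perturbtopics
Title: Topic-Model Analysis and Effect Ranking for Single-Cell CRISPR Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated pipeline for pooled single-cell CRISPR screening data
    (Perturb-seq, CRISP-seq, CROP-seq). Provides cell quality control, a
    similarity-based filter for cells that escaped editing, selection of highly
    dispersion differentially expressed genes, a collapsed-Gibbs latent
    Dirichlet allocation representation of cells as mixtures of functional
    topics, automatic topic-number selection, gene-set annotation of topics,
    and bootstrap t-statistic scores that rank perturbations by overall effect,
    by topic-specific effect, and by effect change between experimental
    conditions. Includes a synthetic-screen generator with planted topic
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp,
    Biostrings,
    BiocGenerics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
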