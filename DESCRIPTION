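Package: picnet
Title: Physical Cell-Cell Interaction Analysis from scRNA-seq Doublets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers physical cell-cell interaction networks in tumour
    microenvironments from the biological doublets of droplet scRNA-seq.
    Calls doublets and their cell-type composition with a random-forest
    classifier trained on synthetic doublets, tests doublet-type enrichment
    against a random-pairing null, scores ligand-receptor communication per
    clinical-outcome group with z-score interaction statistics, extracts
    interaction-induced gene programs by two-stage latent Dirichlet
    allocation topic modelling, derives doublet-specific gene signatures
    from differential expression, and scores transcription-factor activity
    with univariate linear models over signed regulons. Ships a synthetic
    data generator with planted ground truth so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    ranger,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
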