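Package: uriexc
Title: Prediction of Urine Excretory Proteins from Sequence Features
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of whether a protein can be excreted
    into urine. Computes a 243-value physicochemical feature vector from an
    amino-acid sequence (composition, CTD descriptors, predicted secondary
    structure content, intrinsic disorder, signal-peptide and membrane
    heuristics, glycosylation motifs, charge and ProtParam-style indices),
    selects discriminative feature values by the F-score statistic, and trains
    a soft-margin support vector machine with a radial-basis kernel via a
    repeated half-split threshold-search procedure. Also provides
    family-proportional negative-set sampling, confusion-matrix and ROC/AUC
    evaluation, a paired tumor-versus-control fold-change statistic with a
    permutation null for nominating candidate urinary biomarkers, and
    synthetic-data generators that exercise the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
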