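Package: tfannotate
Title: Sequence-Based Identification, Structural Classification and
    DNA-Motif Transfer for Transcription Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A four-step workflow for annotating transcription factors (TFs)
    from protein sequence alone: (1) discrimination of TFs from other
    proteins and (2) prediction of their structural superclass, both driven
    by homology-derived bit-score percentile features and a set of
    comparison encodings (PSSM profile, k-mer, pseudo amino acid, functional
    domain composition) combined with pluggable classifiers, one-vs-rest or
    exhaustive error-correcting output codes; (3) identification of
    DNA-binding domains by Gene Ontology subtree filtering of domain-scan
    output; and (4) transfer of position frequency matrices (PFMs) from
    annotated TFs selected by support vector regression on DNA-binding
    domain similarity features, with Smax log-odds motif similarity,
    outlier filtering and guide-tree progressive motif merging. Includes
    stratified nested cross-validation with threshold-averaged ROC curves,
    a PFM-transfer evaluation protocol, and a synthetic-data generator so
    the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
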