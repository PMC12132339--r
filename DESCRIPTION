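Package: fomopipe
Title: Behavioral-State and Neural Analysis of Trial-Structured Social Exclusion Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for trial-structured social-exclusion ("FOMO")
    sessions in mice: pose-derived behavioral feature extraction, supervised
    attending-behavior detection by heatmap regression with non-maximum
    suppression, hidden-Markov behavioral state segmentation with model
    selection, peri-event calcium imaging analysis (z-scored PSTHs, Wilcoxon
    responsiveness, Ward ensemble clustering, train-set-only PCA population
    decoding, trajectory geometry), and two-channel fiber photometry
    processing (reference regression, trial AUC, random-forest decoding).
    Includes seeded synthetic-data generators with planted ground truth for
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    zoo,
    pROC,
    glmnet,
    randomForest,
    e1071,
    jsonlite,
    yaml,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
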