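Package: triagemap
Title: Document Triage and Ontology-Node Mapping for Interaction Curation
Version: 0.1.0
Authors@R: person("Curation", "Tools", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A two-part literature-mining toolkit for protein-protein
    interaction (PPI) curation support. The triage component classifies
    articles as PPI-relevant or not from title and abstract, using
    unigram/bigram features selected by mutual information or chi-square
    score and classified with multinomial naive Bayes or a
    polynomial-kernel support vector machine. The mapping component
    assigns interaction-detection-method nodes of a PSI-MI style OBO
    ontology to full-text articles by classifying article-node pairs over
    twenty-one lexical match features, and extracts an evidence sentence
    for every assigned node. Includes the full evaluation-metric suite
    (micro F1, MCC, interpolated AUC iP/R, accuracy, sensitivity,
    specificity), seeded synthetic corpus generators, and a command-line
    interface with named run presets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
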