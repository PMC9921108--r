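Package: mtqsar
Title: Multi-Target QSAR Modelling of Drug-Enzyme Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-target machine-learning QSAR modelling of drug-enzyme
    interactions. Computes classic topological molecular descriptors from
    SMILES, augments them with per-enzyme-subclass moving-average features
    (class means and deviations) so a single classifier handles many targets,
    selects descriptors by forward-stepwise logistic screening, trains a
    two-output multi-layer perceptron with a repeated 70/30 split protocol,
    and evaluates with confusion statistics, Matthews correlation and ROC
    curves. Includes batch SMILES prediction with per-family confidence
    tables and a seeded synthetic-data generator with planted multi-target
    structure for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: ChemmineR, ChemmineOB, igraph, nnet, jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), pROC, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
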