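Package: navvar
Title: Predicting Functional Changes to the Cardiac Sodium Current from
    SCN5A Missense Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for relating missense variants in the cardiac sodium
    channel gene SCN5A to functional changes in the sodium current I_Na.
    Models the Nav1.5 protein as ordered topological regions (termini,
    transmembrane segments, linkers), enumerates every amino-acid
    substitution reachable by a single nucleotide change in a coding
    sequence, computes physico-chemical substitution features (Grantham
    distance, Gonnet-250 score, property deltas) and per-position
    conservation from a multiple alignment, resolves heterogeneous
    per-publication electrophysiology reports into per-variant labels by
    majority vote and experimental-condition preference rules, computes
    relative mutation densities per region, and evaluates classifiers of
    electrophysiological outcome with Zero-R baselines, Matthews
    correlation, ROC/AUC and information gain. Includes a synthetic
    report generator emulating the statistical structure of the curated
    literature database so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    e1071,
    jsonlite,
    nnet,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
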