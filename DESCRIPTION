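Package: aopke
Title: Quantitative Key-Event Analysis for Mitochondrial Neurotoxicants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis framework for adverse-outcome-pathway (AOP) guided in
    vitro neurotoxicity screening of mitochondrial respiratory-chain
    inhibitors. Implements constrained four-parameter Hill
    concentration-response fitting with analytic effective concentrations
    (ECx) and bootstrap benchmark concentrations (BMC); a negative-binomial
    Wald differential-expression pipeline for targeted-sequencing count
    matrices (median-of-ratios normalization, moderated dispersions,
    Benjamini-Hochberg control); transcriptomic point-of-departure
    statistics built on differentially-expressed-gene counts (positive
    control normalized DEG response, degree of gene-expression homeostasis);
    specificity-of-neurotoxicity classification and key-event sensitivity
    ratio concordance matrices; and oxygen-consumption-rate inhibition
    arithmetic for extracellular-flux respirometry. A synthetic-data module
    generates Hill-shaped assay readouts, planted differential-expression
    count matrices and key-event panels with known ground truth, so that
    every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
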