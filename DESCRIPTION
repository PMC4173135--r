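Package: qepest
Title: Quantitative Estimates of Pesticide-Likeness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits shared Gumbel-peak desirability functions to the
    distributions of six molecular descriptors (molecular weight, logP,
    hydrogen-bond acceptor and donor counts, rotatable bonds, aromatic
    rings) over herbicide, insecticide and fungicide reference sets, and
    scores arbitrary molecules on a continuous 0-1 likeness scale (QEH,
    QEI, QEF and the fused QEPmax/QEPavg) by the unweighted geometric
    mean of the per-descriptor desirabilities. Includes the classical
    rule-based comparators (Lipinski, Tice, Hao), histogram bin-width
    optimization, ROC/AUC evaluation utilities, a synthetic population
    generator for end-to-end validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
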