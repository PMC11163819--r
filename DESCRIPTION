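Package: edscan
Title: Strand-Aware A-to-I RNA Editing Detection and Differential Editing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for transcriptome-wide A-to-I RNA editing
    analysis from per-site pileup counts: strand-aware editing-site detection
    with a multi-rule artifact filter cascade and known-site whitelist rescue,
    binomial GLM likelihood-ratio differential editing between case and control
    groups, cross-dataset consensus, weighted co-editing network construction
    with module eigengenes and degree-centrality hub extraction, and clinical
    association and ROC analysis for editing biomarkers. Includes a synthetic
    data generator that plants editing sites, germline SNPs and sequencing
    artifacts with known truth so every stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
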