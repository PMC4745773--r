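Package: stromascreen
Title: Prioritization of Stroma-Derived Secretome Biomarkers from iTRAQ
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for prioritizing stroma-derived secreted
    protein biomarkers from comparative fibroblast versus cancer-epithelium
    secretome proteomics. Implements target-decoy protein-level FDR
    filtering of identification tables, replicate-consistent enrichment
    calls from 8-plex iTRAQ channel ratios, priority-ordered subcellular
    localization classification of the secretome, a vote-count screen over
    public microarray analyses, and the downstream biomarker evaluation
    statistics (Kaplan-Meier/log-rank survival, immunohistochemistry
    positivity scoring, Fisher's exact association, ROC curve and optimal
    cutoff selection). A synthetic-data module generates every input with
    planted ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
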