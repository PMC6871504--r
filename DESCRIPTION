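Package: methylMCFS
Title: Methylation Subtype Discovery via Monte-Carlo Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for discovering DNA-methylation
    subtype signatures from 450K-style beta-value matrices: Monte-Carlo
    feature selection (MCFS) ranks probes by a relative-importance score
    aggregated over decision-tree ensembles; incremental feature
    selection (IFS) evaluates nested top-k probe prefixes with
    cross-validated multiclass classifiers (one-vs-rest linear SVM,
    random forest) scored by per-class accuracy, overall accuracy and
    the multiclass Matthews correlation coefficient; optimum and compact
    probe sets are selected from the IFS curve; and the selected probes'
    genes are tested for term over-representation with the
    hypergeometric distribution and Benjamini-Hochberg FDR control.
    Includes a synthetic-data generator with planted discriminative
    probes and a planted enriched term so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
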