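Package: cernaflow
Title: Paired-Design ceRNA Network Inference from Multi-Layer RNA-seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a tumour/normal competing-endogenous-RNA
    (ceRNA) discovery workflow for paired bulk RNA-seq count data. Provides trimmed
    mean of M-values (TMM) normalization, a per-pair conditional negative-binomial
    exact test for designs without replicates, assembly of lncRNA-miRNA-mRNA ceRNA
    triads under database-intersection, direction-concordance, Pearson-correlation
    and miRNA-response-element filters, hypergeometric over-representation analysis,
    2^(-ddCt) relative quantification, and leave-one-out cross-validated ROC/AUC
    diagnostics. A synthetic-data generator plants ground-truth differential
    expression and ceRNA triads so that every stage of the pipeline can be verified
    end to end without access to patient data.
License: MIT
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
    edgeR,
    pROC
Config/testthat/edition: 3
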