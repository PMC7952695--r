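Package: CutpointScreen
Title: Genome-Wide Optimal Survival Cutpoint Screening for Prognostic
    Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-wide discovery of prognostic biomarkers by optimal
    survival cutpoint selection. For every gene in a z-scored expression
    matrix the expression threshold that maximizes the two-group log-rank
    separation of recurrence-free survival is selected, standardized as a
    maximally selected rank statistic (Contal-O'Quigley), and assigned a
    supremum-Brownian-bridge p-value that corrects for the cutoff search.
    Genes are then filtered by significance and by the cutoff z-score band
    (over- / under-expression) and partitioned into shorter- and
    longer-survival lists. Includes a from-scratch survival core
    (Kaplan-Meier, log-rank, Cox proportional hazards with Efron ties,
    Bonferroni adjustment), H-score quantification of immunohistochemistry
    intensity-category counts with the highest-field rule, a generic
    hypergeometric overrepresentation and activation z-score stand-in for
    pathway analysis, a synthetic-cohort generator with planted cutpoint
    effects under proportional hazards, and TSV/GMT readers for
    cBioPortal-style inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    yaml,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
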