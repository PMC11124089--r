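Package: glycodrug
Title: Drug Nomination and Expression Biomarker Discovery for
    High-Glycolysis Metastatic Prostate Cancer
Version: 0.1.0
Authors@R:
    person("Mercer", "Lane", email = "mercer.lane@example.org",
           role = c("aut", "cre"))
Description: A reusable analysis pipeline that nominates candidate drugs for
    metastatic castration-resistant prostate cancer (mCRPC) tumors with high
    glycolysis and/or oxidative phosphorylation (OXPHOS) activity, and
    discovers expression biomarkers for the nominated drugs. The pipeline
    scores tumors with single-sample gene-set variation scores, imputes
    drug response from cell-line screens via batch-harmonized ridge
    regression, screens score-response associations under FDR control,
    applies a four-filter candidate cascade, ranks protein-protein
    interaction hub genes by twelve topological centrality methods with
    tiered consensus, and stratifies patient survival by biomarker
    expression. A synthetic-data module generates every pipeline input with
    planted ground truth so each stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    survival,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
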