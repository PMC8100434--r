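Package: copath
Title: Co-Occurring Pathway Alteration Analysis for Immunotherapy Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Stratifies immunotherapy-treated tumor cohorts by co-occurring
    alteration of the NOTCH oncogenic signaling pathway and multiple DNA
    damage response (DDR) pathways, and quantifies the clinical consequences
    of that stratification. Provides readers for MAF-style somatic mutation
    tables, clinical tables and GMT gene-set catalogs; a sample-by-pathway
    alteration matrix with the NOTCH+/co-DDR+ (GoodBenefit) rule; tumor
    mutational burden computation; Kaplan-Meier, log-rank and Cox
    proportional-hazards analyses; single-sample GSEA immune-infiltration
    scoring with Ward clustering and pre-ranked permutation GSEA; and a
    seeded synthetic-cohort generator with planted hazard ratios and immune
    signals so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
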