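Package: crstrio
Title: Trio Exome Diagnostic Workflow for Craniosynostosis Cohorts
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Post-annotation analysis workflow for tiered genetic testing of
    craniosynostosis cohorts sequenced as trios: depth-ratio genotype
    recalibration, trio inheritance assignment with compound-heterozygote
    pairing, a two-part research pipeline intersecting deleteriousness and
    frequency filters with phenotype-driven prioritizer ranks, candidate-gene
    catalog matching with OMIM inheritance-model concordance, per-patient
    diagnostic triage from ACMG pathogenicity classes, diagnostic-yield and
    exact contingency-table statistics, and a tiered panel-versus-exome cost
    model.  Ships a seeded synthetic-cohort generator that emulates a
    two-stage (gene panel, then whole-exome) testing history with spiked-in
    diagnostic and candidate variants for end-to-end exercise of the
    workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
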