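Package: mdsrisk
Title: Prognostic Risk Stratification and Mutation Association Analysis for Myelodysplastic Syndromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognostication of myelodysplastic syndromes (MDS)
    cohorts: parsing of ISCN karyotype strings and IPSS-R cytogenetic risk
    classification, IPSS-R scoring with a lower/higher-risk dichotomy at 3.5
    points, a mutation-augmented M-IPSS-R score with Low/Intermediate/High
    tiers and a reclassification report against IPSS-R, contingency-table
    association tests (Fisher exact, Pearson chi-square) between gene
    mutations and patient groupings, Kaplan-Meier/log-rank and Cox
    proportional-hazards survival analysis, and a seeded synthetic cohort
    generator that emulates a 152-patient MDS study population for
    end-to-end pipeline testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
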