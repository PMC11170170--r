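Package: magescreen
Title: Biomarker Screening Analytics for HLA-Restricted MAGE-A4 TCR T Cell Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for the biomarker screening analyses that determine patient
    eligibility for MAGE-A4-targeted, HLA-A*02-restricted T cell receptor (TCR)
    T cell therapies. Implements HLA-A allele and genotype-list parsing with
    P-group resolution and inclusion/exclusion eligibility rules, exact one-sided
    binomial lower confidence bounds (Clopper-Pearson and Wilson) for typing
    concordance validation, immunohistochemistry P-score computation with
    positivity calling and prevalence/agreement summaries, three-parameter
    log-logistic dose-response fitting with fold-change potency classification,
    logistic-regression covariate analysis reported as odds ratios with Wald
    confidence intervals, and a seeded synthetic cohort generator that exercises
    the full screening pipeline end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
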