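Package: medocr
Title: Combined Mediterranean and Western Diet Adherence Scoring for Food Frequency Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring semi-quantitative food frequency questionnaire
    (FFQ) data on a single adherence axis running from the Western diet (WD)
    to the Mediterranean diet (MD). Implements the MEDOC combined adherence
    score (-20 for full WD adherence to +20 for full MD adherence), built
    from per-food cut-off rules with behaviour-based bonus/penalty
    modifiers, together with two reference Mediterranean-diet scorers used
    for validation (the MedDietScore, 0-55, and the literature-based
    MEDILITE score, 0-18). Includes a test-retest reliability toolkit
    (Pearson and Spearman correlations with Fisher-z confidence intervals,
    intraclass correlation, simple and weighted Cohen's kappa, and
    conventional interpretation bands), and a synthetic respondent generator
    that emulates cohorts spanning the WD-MD axis with paired test-retest
    administrations, so the full validation workflow runs without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    lme4,
    e1071,
    optparse
Config/testthat/edition: 3
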