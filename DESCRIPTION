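Package: phqtrends
Title: Dual-Source Surveillance of Depressive Symptom Trends from Social
    Media and Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring population-level depressive symptoms from
    two parallel data sources: short social-media posts screened with a
    PHQ-8-anchored German keyword lexicon (seed words expanded by
    PPMI-weighted co-occurrence embeddings, exact-match keyword detection,
    first-person self-reference filtering) and questionnaire self-reports
    (dichotomized, survey-weighted weekly proportions). Both streams are
    aggregated to weekly per-symptom series around the first German
    COVID-19 social-contact ban, modelled with covariate-adjusted weighted
    regressions (fourth-degree polynomial smoothing, period-level
    predictive margins with delta-method intervals, Wald period tests and
    pairwise contrasts), and compared across sources by Spearman rank
    correlation with an exploratory integer-week lag scan. A synthetic-data
    module generates survey cohorts, tweet streams and enrichment corpora
    with the statistical structure the analysis assumes, so the whole
    pipeline runs and is testable without access to the restricted study
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
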