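---
title: "Methods: dual-source monitoring of depressive symptom trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-source monitoring of depressive symptom trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phqtrends)
```

## The problem and the two data streams

Population surveys measure depressive symptoms carefully but slowly; social
media produces a continuous stream of self-reports of unknown validity. This
package implements a pipeline that renders both streams comparable around a
discrete public-health event — the first German COVID-19 social-contact ban
(calendar weeks 12–18 of 2020, inside a study window of ISO weeks 1–31) —
and quantifies how well their weekly trajectories agree.

Five PHQ-8 symptom domains are tracked: diminished interest, depressed mood,
insomnia/hypersomnia, fatigue/energy loss, and worthlessness/guilt
(`phq_symptoms`). The remaining PHQ-8 items (appetite, concentration,
psychomotor change) are not tracked: their social-media keyword signal is
too sparse or too ambiguous for exact matching.

The two observation units are:

* **Survey records**: PHQ-8 item responses on the 0–3 frequency scale, with
  calendar week, sex, age group and a survey weight. Responses are
  dichotomized (`dichotomize()`): 0 stays "not at all affected", any of
  1–3 becomes "affected", which puts questionnaire frequencies on the same
  footing as keyword mention frequencies.
* **Tweet records**: short texts with timestamp, user id, a retweet flag
  and demographic attributes. Demographics arrive as input fields; the
  package makes no attempt to infer them from text.

## Lexicon construction

Symptom detection is lexicon-based and deliberately transparent:

1. **Seeds** (`build_seed_sets()`): a small curated set of German keywords
   per symptom, anchored to the questionnaire item wording (for depressed
   mood: *Niedergeschlagenheit*, *Schwermut*, *Hoffnungslosigkeit*).
2. **Enrichment** (`train_embedding()`, `expand_lexicon()`): seeds are
   expanded with corpus-derived neighbours. The embedding backend is
   PPMI-weighted co-occurrence counts factorized by truncated SVD — chosen
   over neural alternatives because it is exactly deterministic (the sign of
   each singular vector is fixed by making its largest-magnitude component
   positive), desk-scale, and swappable behind the `embedding_space`
   contract. A token's neighbours are ranked by cosine similarity;
   candidates with similarity at least `tau` (default 0.4) are admitted, at
   most `k` (default 25) per seed word, ties broken lexicographically.
   Neither threshold is canonical: both are surfaced in the configuration,
   and an allow/deny list stands in for manual curation.
3. **Matching** (`match_keywords()`): exact token-sequence matching after
   Unicode-aware lowercasing and hashtag-`#` stripping. No stemming,
   lemmatization, compound splitting or negation handling — an exact-match
   contract, which stemming would silently violate. Multi-word keywords
   ("schlechte stimmung") must occur as contiguous token runs; for
   embedding training they are merged into single tokens.

A note on what the embedding can and cannot certify: distributional
similarity is *second-order*. Two words become neighbours because they share
contexts, not because they co-occur with each other — two tokens that only
ever co-occur with each other have orthogonal context profiles and near-zero
cosine. The synthetic enrichment corpus therefore plants related words in
the *same contexts* as their seeds, which is the mechanism a real forum
corpus would provide at scale.

## Tweet filtering

`classify_tweets()` applies a fixed-order pipeline, reporting retention at
every stage so no data loss is silent:

1. drop records outside the study window (malformed timestamps are rejected
   with a warning, never a crash);
2. drop retweets — the `is_retweet` flag *or* a leading `"RT @"` prefix;
   quoted tweets count as originals;
3. exact keyword matching; non-matching records are dropped;
4. self-reference filtering (`detect_self_reference()`): a symptom mention
   only counts as a self-report if the text carries a first-person pronoun
   (*ich*, *mir*, *mich*, *mein-*, *wir*, *uns*, *unser-*) or first-person
   verb form (*bin*, *habe*, *fühle*, *leide*, …); token-level and
   case-insensitive, never substring. Both lists are configurable.

Weeks follow ISO 8601 ("Kalenderwoche"), the German calendar-week standard.
`aggregate_weekly()` reports, per symptom and week, the mean number of
tweets per day: the week's count divided by the days of that week inside
the window (edge weeks 1 and 31 of the 2020 window cover 5 and 4 days and
are flagged `partial_week`). A tweet matching several symptoms counts once
in each matched series — series are per-symptom, so this is the coding under
which per-symptom margins are interpretable. Symptoms averaging strictly
fewer than 12 tweets/day over the window are excluded from modelling
(`exclude_rare_symptoms()`), with the exclusion reported.

Survey records are aggregated (`aggregate_weekly_weighted()`) as
weight-normalized weekly proportions, available-case per item (a missing
response drops the respondent from that item only). Weeks with no
respondents are flagged missing, never imputed as zero.

## The regression models

For each retained symptom and each source, three nested model shapes share
one fitting surface (`fit_symptom_model()`):

* covariates only: sex, age group, and sex × age interaction (treatment
  coding; references: male, youngest age group);
* the covariates plus a **fourth-degree polynomial** in calendar week,
  entered as centered powers `(week − w̄)^1..4` — centering is purely for
  numerical conditioning, fitted values are invariant to it. Four degrees
  are enough to bend through a dip-and-recovery shape over 31 weeks without
  chasing weekly noise; fewer than 5 distinct weeks makes the term
  unidentifiable and is an error;
* the covariates plus the **three-level period factor**
  (before/during/after the ban, reference *before*), used for period
  inference.

The survey outcome (binary, affected) is fitted by weighted logistic
regression via IRLS; the quasi-binomial variant is used so that non-integer
survey weights are handled without protest, which leaves the point estimates
untouched. The twitter outcome is the tweets/day count in each week × sex ×
age cell, fitted by weighted least squares on the identity scale — margins
then live on the same tweets/day scale the series are reported on, with no
log transform. Cells are unweighted by default; a `volume_weights` switch
weights them by tweet count for sensitivity analysis. Both families use
heteroskedasticity-robust (HC1) sandwich covariance by default: the survey
weights are not frequency weights, and counts modelled as gaussian are
heteroskedastic by construction. Convergence (relative deviance change
below `1e-8`, at most 100 iterations), separation (fitted probabilities
within `1e-8` of 0/1) and rank deficiency are all surfaced explicitly.

Without the survey's design variables (strata, PSUs), design-based variance
estimation is not possible; weighted estimation with robust variances is
the stated approximation, and `wald_period_test(df2 = )` accepts a
design degrees-of-freedom argument that turns the joint chi-squared test
into a design-adjusted F when cluster information exists.

**Predictive margins** (`predictive_margins()`) use observed-covariate
averaging: the focal variable (period, or week) is set to a level for every
observation, the response-scale prediction is averaged with the estimation
weights, and the delta method applied to that average gives the standard
error; intervals are normal-based 95% CIs. **Pairwise period contrasts**
(`pairwise_contrasts()`) are margin differences with delta-method SEs that
use the full coefficient covariance (the two margins are correlated); no
multiplicity correction is applied, matching the per-comparison reporting
convention for period contrasts.

## Cross-source correspondence

The two weekly series live on incomparable scales (proportions vs counts)
and their relation need not be linear, so agreement is measured by
Spearman rank correlation (`spearman_rho()`): average ranks for ties,
Pearson correlation of the rank vectors, p-value from the t approximation
on n − 2 df (n ≈ 31 weeks). An exact permutation p-value by full
enumeration is available for n ≤ 8; beyond that, enumeration (n! orderings)
stops being desk-scale and the t approximation is the default anyway.

`correlate_sources()` correlates the *smoothed* weekly margins (the
polynomial-model predictions) by default — raw weekly values are available
as a sensitivity option. Lag 0 is the headline figure. The integer-week
**lag scan** (default −4…+4) shifts the twitter series against the survey
series and reports the lag maximizing rho; a negative best lag means the
twitter signal leads. The scan is this package's operationalization of a
visual lead–lag observation and is labelled exploratory: it is a
descriptive maximum, not a test.

## The synthetic-data generators

`generate_survey()`, `generate_tweets()` and `generate_corpus()` produce
data with the statistical structure the analysis assumes, so that every
downstream stage is testable without the restricted study data.

* The **survey cohort** (default n = 9011, 51.7% female, 50+ modal age
  group) draws calendar weeks uniformly, mean-1 log-normal weights
  (σ_log = 0.5), and graded item responses whose affected-probability
  follows a logistic model: symptom base rate + period offset + demographic
  offsets. Default base rates (0.38/0.27/0.50/0.54/0.14) and period
  log-odds offsets are set to reproduce the published period-level margin
  pattern of the survey source; demographic offsets encode the elevated
  risk of young adult women (+0.3 female, +0.2 ages 18–24, +0.3 their
  interaction).
* The **tweet stream** (default 80,000 users) assigns each user one week,
  1–10 tweets (96% single-tweet, geometric tail — the 1–10 support is a
  hard invariant), sex/age from the platform-shaped marginals (83.9%
  female, 18–24 modal), and per-tweet symptoms from a mixture whose shares
  and period log-rate offsets default to the published tweet-side
  composition (fatigue most common at ~35%, worthlessness rarest at ~6%).
  The default user count is chosen so that the retained stream lands on the
  published per-symptom tweets/day scale (~130/day fatigue, ~21–30/day
  worthlessness); the sample description and the printed daily-count scale
  are not mutually consistent in the source material, and the generator
  privileges the daily-count scale that the models actually consume.
  Texts are minimal German carrier sentences containing exactly one
  lexicon keyword — the matcher is exact-match, so fluency is irrelevant —
  first-person with probability `self_reference_rate` (0.96) and built
  strictly inside the self-reference rule vocabulary, so the generator's
  ground-truth flag and the detector must agree exactly. Retweets
  (rate 0.03) are flagged and `"RT @…"`-prefixed. Tweets of one user are
  assigned independently; no within-user temporal correlation is modelled.
* The **enrichment corpus** emits short documents in which each planted
  related word shares a symptom-specific context pool with its seeds, plus
  distractor documents over a disjoint pool, so embedding expansion can —
  and, in tests, must — recover exactly the planted words.

All three generators are byte-deterministic given `rng_seed`, and restore
the caller's RNG state.

What the generators deliberately do **not** emulate: realistic Twitter
language (emoji, spelling variation, irony), network or bot structure,
seasonal components, within-user correlation, or region effects beyond an
opaque label. Passing tests on synthetic data therefore certify the
*pipeline machinery* — filtering, aggregation, estimation, inference,
correlation — not the field validity of keyword-based symptom detection.

One consequence worth stating: the two sources are generated with their own
(published) period patterns plus independent noise, and for some symptoms
those patterns diverge between sources — as they did in the study itself.
Synthetic cross-source rank correlations are therefore *not* calibrated to
any published range; they vary by symptom and seed, and the package reports
whatever the data imply.

## Numerical and design choices

* Reference coding throughout: male, youngest age group, period *before*;
  the "15–17" (survey) and "10–17" (twitter) youngest groups are harmonized
  to a shared "<18" level only where effects are applied across sources.
* Expansion ties broken lexicographically; duplicate expansions keep the
  highest cosine; seeds always outrank expansions.
* Degenerate inputs are contracts, not accidents: constant vectors leave
  Spearman's rho undefined and flagged; a symptom at exactly the 12/day
  threshold is retained (the exclusion is strict); a lag with under 3
  overlap weeks is skipped with a log entry; an all-missing survey week is
  flagged and skipped by the models.
* Problem sizes in the test-suite: oracle equivalences run at n ≤ 30
  (logistic), ≤ 12 (Spearman, 1000 draws) and vocabularies ≤ 500 tokens;
  parameter recovery uses 200 replicates of n = 5000; the Wald size check
  uses 1000 null replicates of n = 600. These sizes make the checks sharp
  while keeping the default suite comfortably interactive.
* The package is organised as an analysis workflow: the numbered scripts
  under `analysis/` are thin narrative drivers over the exported functions,
  and `run_pipeline()` executes the same stages end-to-end from a single
  seeded configuration. Subcommand-style use is covered by running the
  stage scripts individually.

## Known limitations

Keyword matching without negation handling cannot distinguish "energielos"
from "nicht energielos"; sentiment and context are out of scope. The
self-reference rules are a high-precision heuristic, exact on the synthetic
templates but necessarily approximate on real text. Survey variance
estimation is robust-weighted, not design-based. The lag scan is
exploratory. And all calibration statements above concern the synthetic
generator's defaults — real survey and social-media data bring sampling and
access biases the generator does not model.
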