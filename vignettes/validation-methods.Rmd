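---
title: "Validating lung cancer risk models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating lung cancer risk models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(lungrisk)
```

This vignette is the package's own account of its science: the models
and statistics it implements, the synthetic world its tests run in, and
the design decisions taken where the design was genuinely open. It
states no empirical result that the test suite does not itself compute.

## 1. What is being validated

Twelve published absolute-risk calculators for lung cancer, each
mapping a subject's epidemiological predictors to the probability of an
incident diagnosis within a model-specific horizon (5, 6, 6.6, 8.7 or
10 years). Six apply to ever smokers only (LCRAT, Pittsburgh, HUNT,
PLCOm2012, NHIS, Bach); six to all adults (LLP v2, LLP v3, OWL, LCRS,
PLCOall2014, LLPi). The package evaluates them through four
mathematical forms:

1. **Direct logistic** — `p = plogis(lp)`.
2. **Cox baseline survival** — `p = 1 - s0^exp(lp)`, with `s0` the
   baseline survivor function at the horizon.
3. **Odds ratio x baseline incidence** (the Liverpool family) — the
   age–sex baseline risk is converted to odds, multiplied by the
   product of the subject's odds ratios, and converted back; capped
   at 1.
4. **Annual recursion with competing mortality** — per year `k` the
   subject faces a lung-cancer hazard `h_lc(k)` (age–sex baseline
   scaled by `exp(lp)`) and a competing mortality hazard `h_m(k)`;
   the cumulative risk is the sum over years of the probability of
   surviving both processes to year `k` and then converting.
   Fractional horizons (6.6, 8.7) contribute the final partial year's
   hazard pro-rata, the simplest discretization that is exact for
   piecewise-constant hazards; a refinement to monthly steps agrees
   with the closed-form constant-hazard limit to 1e-3 (tested).

Each model ships as a declarative JSON spec (form, intercept, terms
with transformation pipelines, baseline tables), decoupling
transcription from engine code. **Transcription honesty:** PLCOm2012
carries its published coefficients (with two documented adaptations:
the race/ethnicity predictor is omitted because the cohort does not
record it, and the cohort's three education levels are mapped onto the
source's six-level scale as 2/3/5). The other eleven specs are
**surrogates**, flagged `surrogate: true` with a `transcription` note:
their form, population, horizon and predictor sets follow the models'
documentation, but the coefficients and baseline tables are
plausible-magnitude stand-ins, because the original supplements are
not distributable with this package and the OWL original is a trained
gradient-boosting model whose weights are out of scope. Nothing in the
test suite depends on surrogate coefficient values; the suite tests
the *engines* against independent oracles and the *pipeline* against
by-construction ground truth.

## 2. Validation statistics

* **AUC**: Mann–Whitney concordance computed from midranks, ties
  counted one half. Tested for exact equality (1e-12) against a
  brute-force pairwise count on hundreds of random cohorts.
* **AUC interval**: DeLong placement-value variance. The method is not
  prescribed by the study design, so it is the package's choice; it is
  checked against a stratified bootstrap on a fixed vector to 0.02.
* **E/O ratio**: expected over observed, `sum(p)/sum(y)`, with the
  Poisson interval `E/O * exp(±z/sqrt(O))`. Values below 1 mean the
  model *underestimates* risk. (Published sources are inconsistent
  about whether "E/O" abbreviates expected/observed or the reverse;
  this package always computes expected/observed.)
* **Calibration bins**: subjects ranked by predicted risk ascending
  and split into four groups of near-equal size; when `n mod 4 != 0`
  the remainder goes to the lowest-risk bins (so n = 10 gives sizes
  3/3/2/2); tied risks keep input order (stable sort), making bins
  deterministic. The top quartile is the "high-risk" group summarized
  by `radial_feature_summary()`.
* **Outcome at horizon t**: event with `time <= t`. Subjects censored
  before `t` are controls by default (`censor_handling = "as_control"`);
  exclusion is available behind the flag. The default matches the
  simplest reading of a registry-linked cohort with near-complete
  follow-up; with the synthetic generator's censoring floor of 10
  years the two options coincide at every model horizon.
* **Six-year evaluation of all models**: each model is evaluated
  against 6-year outcomes using its native-horizon risk as the score
  and expectation, with no time rescaling — the documented default,
  since no rescaling procedure is described for the source analysis.

## 3. Missing data

Missingness is confined to six fields (smoking years, quit years,
cigarettes/day, BMI, education, height). `mice_impute()` is a compact
chained-equations implementation: predictive mean matching (5-donor
window in sorted predicted values) for continuous fields, ordinal
(proportional-odds) regression for education with a marginal-draw
fallback, ten cycles per imputation. Structural rules are enforced:
smoker-only fields are never imputed for never smokers, and a current
smoker's quit years are identically zero. Estimates are pooled by
Rubin's rules (`T = W + (1 + 1/m) B`); AUC is pooled on the
probability scale with its DeLong variance, E/O on the log scale with
variance `1/O`. Pooling m imputed copies of a complete cohort
reproduces the single-cohort statistics exactly (tested).

## 4. The synthetic cohort: a stated world

Real subject-level data for the motivating cohort are not public, so
the generator reproduces that cohort's *published marginal structure*
by construction, within four strata (ever/never smoker x case status;
sizes 327/5,499/392/24,186):

* every categorical cell count is reproduced exactly (labels allocated
  deterministically, then shuffled under the seed);
* continuous variables are truncated normals with the published
  mean/SD, restricted to the subject's assigned category bin where the
  variable is also tabulated in groups (ages are floored to integers);
* pack-years are derived from the identity `cpd/20 x years` and
  rescaled per stratum to the published mean, with the factor clamped
  to [0.8, 1.25] so the 25% soft identity always holds;
* case event times reproduce the published cumulative schedule exactly
  (71/71/88/101/176 ever-smoker events at 5/6/6.6/8.7/10 years;
  74/74/94/108/179 for never smokers); the published alternative
  schedule (69 ever-smoker events at 5 years) is available as
  `event_schedule = "alternative"`; non-cases are censored uniformly
  on [10, 19.3] years, matching ~20 years of follow-up;
* exactly 382 subjects receive one missing value each among the six
  eligible fields, MCAR under the seed.

Three deliberate deviations/choices, fixed before any test was run:

* **Within-stratum independence.** Only marginals are published, so
  predictors are sampled independently within strata. Consequences: a
  synthetic cohort carries weaker predictor–outcome association than
  the real one, so AUC and E/O computed on it characterize the
  *machinery*, not the published models' real-world performance. A
  green validation test establishes that the statistics are computed
  correctly, nothing more.
* **Smoking timeline consistency.** Initiation age is derived as
  `age - smoking_years - quit_years` (clamped at 8) instead of drawn
  from its published mean/SD, so every smoking history is physically
  possible; the published mean (~22) is approximately recovered
  (~20–21). Smoking-years group labels are repaired by marginal-
  preserving swaps when an assignment would be infeasible for a
  subject's age and quit status.
* **Ground-truth risk scale.** `ground_truth_spec()` (used by
  `risk_structure` mode and the self-calibration tests) has a mean
  absolute risk near 10%, an order of magnitude above any real lung
  cancer calculator. This is intentional: with ~3,000 expected events
  the Monte-Carlo spread of E/O is ~2%, so the [0.93, 1.07]
  self-calibration band is a ~4-sigma test; at a realistic 1% risk the
  band would be only ~1.2 sigma and the test would be noise. The scale
  was chosen from this power calculation, not adjusted after running.

## 5. Screening criteria and the count-matched comparison

Boundary inclusivity follows each criterion's printed symbols exactly
(USPSTF: age 50–80, quit <= 15 years, >= 20 pack-years; NELSON: age
50–74, quit <= 10, strictly more than 15 cigarettes/day for strictly
more than 25 years or > 10 for > 30; T/CPMA: mandatory age 50–74 plus
any of five risk clauses). Two T/CPMA clauses need proxies because the
cohort lacks their native variables: passive smoking (recorded as
hours/day, not years) defaults to `>= 1 hour/day` and is a
configurable threshold; occupational carcinogen exposure narrows to
the asbestos field, the only occupational variable available. Both
proxies are explicit, documented and swappable.

For the comparison, each model's threshold is the `n`-th largest risk
where `n` is the criterion's selection count; ties at the threshold
are dropped by ascending subject id until exactly `n` remain. The rule
is the package's own (published model counts occasionally one below
the criterion count imply *some* drop rule existed, but none is
described); ours is deterministic and tested under adversarial ties.
Never-smoker panels run only the six all-population models and the
T/CPMA criterion — the smoking-based criteria select nobody there.

## 6. Numerical and degenerate-input policy

* Risks are clamped to [0, 1] only where a form can exceed it (odds
  cap; per-year hazard cap `h0 * exp(lp) <= 1`).
* AUC requires at least one case and one control; E/O requires
  `O > 0`; calibration bins require `n >= 4`; Rubin pooling requires
  `m >= 2`. All are hard errors, not silent NAs.
* Age–sex baseline tables clamp out-of-range ages to the nearest band;
  specs may declare `truncate` transforms for out-of-range predictors.
* CSV round-trips are exact: generated continuous values are rounded
  to 4 decimals so the text representation is lossless; missing cells
  are empty (configurable sentinel on write; the em-dash is also read
  as missing).
* All randomness flows from explicit integer seeds; the pipeline's
  report bundle is byte-identical under a fixed config and seed.

## 7. Known limitations

* Surrogate coefficients (all models except PLCOm2012) reproduce each
  model's structure, not its published point predictions; conclusions
  about the *relative* merit of the published calculators cannot be
  drawn from this package's synthetic runs.
* The generator does not model joint predictor correlations beyond the
  stratum structure, nor secular trends in follow-up.
* The competing-mortality tables bundled with the recursion-form specs
  are synthetic life-table-scale values, labelled as such in the spec
  files.
* Criteria proxies (T/CPMA clauses c and e) narrow the printed
  definitions; sensitivity of selection counts to the passive-smoking
  threshold is exposed through the function argument rather than
  hidden.
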