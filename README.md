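# lungrisk

External validation machinery for epidemiological lung cancer risk
prediction models, and their comparison against low-dose CT screening
eligibility criteria.

## The problem

Lung cancer screening programmes must decide *who* to scan. Two
families of selection rules compete:

* **eligibility criteria** — boolean rules on age and smoking history
  (the Chinese T/CPMA 013-2020 standard, USPSTF-2021, and the NELSON
  trial criteria); and
* **absolute-risk calculators** — regression models that convert
  epidemiological predictors into a probability of developing lung
  cancer within a stated horizon, with a screening threshold on that
  probability.

Judging which rule finds more future cases requires external
validation on a cohort the models never saw: **discrimination** (can
the model rank cases above non-cases?), **calibration** (does the
predicted probability match observed incidence?), and a
**count-matched comparison** (when a model is allowed to select exactly
as many people as a criterion, does it capture more cases?). This
package implements that entire workflow for twelve published
calculators (LCRAT, LLP v2/v3, Pittsburgh, HUNT, OWL, LCRS, PLCOm2012,
PLCOall2014, NHIS, LLPi, Bach), targeted at cohorts of ever and never
smokers aged 45+ such as large Chinese community cohorts, where nearly
40% of lung cancer arises in never smokers.

## The statistics at the core

* Discrimination: AUC as the Mann–Whitney concordance
  P(score_case > score_control), ties ½, with a DeLong variance
  interval.
* Calibration: E/O = Σᵢ p̂ᵢ / Σᵢ yᵢ with the Poisson interval
  E/O·exp(±z/√O), plus risk-quartile calibration bins (the top quartile
  is the "high-risk" group fed into feature summaries).
* Missing data: multiple imputation by chained equations (predictive
  mean matching; ordinal regression for education) pooled by Rubin's
  rules, T = W + (1 + 1/m)B.
* Risk engines, one per model form:
  - logistic: p = expit(β₀ + Σβⱼxⱼ)
  - Cox baseline survival: p = 1 − S₀(t)^exp(lp)
  - odds-ratio × baseline incidence (LLP family): odds' = odds₀·Πⱼ ORⱼ
  - annual recursion with competing mortality:
    p = Σ_k [Π_{j<k} (1−h_lc(j))(1−h_m(j))] · h_lc(k)
* Count matching: the threshold is the n-th largest risk with a
  deterministic ascending-id tie-drop so each model selects *exactly*
  as many subjects as the criterion.

Because the source cohort is not public, the package ships a synthetic
cohort generator that reproduces the published stratified marginal
table *by construction*: 30,404 subjects, 5,826 ever smokers, 719
cases, exact categorical cell counts per (smoking group × case status)
stratum, the published cumulative event schedule, and 382 subjects with
injected missingness. A `risk_structure` mode simulates outcomes from a
known model so the validation statistics can be tested against ground
truth. Model coefficients live in declarative JSON specs under
`inst/models/`; PLCOm2012 carries its published coefficients, the other
eleven are clearly flagged surrogates (correct form, population,
horizon and predictor set; plausible-magnitude coefficients) — see the
vignette.

## Worked example

```r
library(lungrisk)
cfg    <- default_cohort_config()
cohort <- generate_cohort(cfg, seed = 1)
cohort
#> <lr_cohort> 30404 subjects; 719 events
#> provenance: generator=lungrisk; mode=marginal_matching; seed=1

ever <- subset_by_smoking(cohort, "ever")
validation_report(ever, registry_list()$PLCOm2012, stratum = "ever")
#> <validation> PLCOm2012 [ever, 6y, n=5826]  AUC 0.756 (0.692-0.821)  E/O 1.643 (1.302-2.073)

compare_all(ever, "uspstf", registry_list()[c("PLCOm2012", "OWL", "Bach")])[, 1:6]
#>        method     model threshold n_selected sensitivity specificity
#> 1 USPSTF-2021      <NA>        NA       2650          NA          NA
#> 2 USPSTF-2021 PLCOm2012    0.0151       2650       0.746       0.549
#> 3 USPSTF-2021       OWL    0.0194       2650       0.873       0.550
#> 4 USPSTF-2021      Bach    0.0148       2650       0.835       0.557
```

Reading the output: USPSTF-2021 selects 2,650 of the 5,826 ever
smokers; each model's threshold (e.g. 1.51% six-year risk for
PLCOm2012) is set so it selects exactly the same number, and
sensitivity/specificity are computed at the model's native horizon.
The AUC (0.76) says the model ranks cases well on this synthetic
cohort; the E/O of 1.64 reflects that the generator samples predictors
independently within strata, so the synthetic cohort carries weaker
predictor–outcome association than a real one — calibration values on
synthetic data characterize the *machinery*, not the published models
(see the vignette for what a green test does and does not establish).

The full pipeline (all models, both smoking strata, imputation,
comparisons, serialized JSON/CSV bundle):

```r
rc <- run_config(models = "all", m = 5, seed = 1, out_dir = "out")
bundle <- run_pipeline(rc)        # 12 ever + 6 never reports
```

A file-based CLI mirroring the pipeline lives at
`inst/cli/lungrisk.R` (`simulate`, `score`, `criteria`, `validate`,
`compare`, `report`, `models` subcommands).

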