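{
  "schema_version": "1.0",
  "name": "PLCOm2012",
  "label": "Prostate, Lung, Colorectal and Ovarian 2012 smoker model",
  "source": "Tammemagi MC et al., N Engl J Med 2013;368:728-736",
  "transcription": "published coefficients; the race/ethnicity predictor is omitted (not recorded in the validation cohort) and education is mapped onto the source 6-level scale as 2/3/5",
  "surrogate": false,
  "population": "ever_only",
  "horizon_years": 6,
  "form": "logistic_direct",
  "intercept": -4.532506,
  "terms": [
    {
      "predictor": "age",
      "coef": 0.0778868,
      "transform": [
        {
          "op": "subtract",
          "value": 62
        }
      ]
    },
    {
      "predictor": "education_level",
      "coef": -0.0812744,
      "transform": [
        {
          "op": "map",
          "levels": {
            "middle_school_or_below": 2,
            "high_school": 3,
            "college_or_above": 5
          }
        },
        {
          "op": "subtract",
          "value": 4
        }
      ]
    },
    {
      "predictor": "bmi",
      "coef": -0.0274194,
      "transform": [
        {
          "op": "subtract",
          "value": 27
        }
      ]
    },
    {
      "predictor": "copd",
      "coef": 0.3553063,
      "transform": []
    },
    {
      "predictor": "prior_cancer",
      "coef": 0.4589971,
      "transform": []
    },
    {
      "predictor": "family_history_lc",
      "coef": 0.587185,
      "transform": [
        {
          "op": "map",
          "levels": {
            "none": 0,
            "first_degree": 1
          }
        }
      ]
    },
    {
      "predictor": "smoking_status",
      "coef": 0.2597431,
      "transform": [
        {
          "op": "map",
          "levels": {
            "never": 0,
            "former": 0,
            "current": 1
          }
        }
      ]
    },
    {
      "predictor": "cigarettes_per_day",
      "coef": -1.822606,
      "transform": [
        {
          "op": "divide",
          "value": 10
        },
        {
          "op": "power",
          "value": -1
        },
        {
          "op": "subtract",
          "value": 0.4021541613
        }
      ]
    },
    {
      "predictor": "smoking_years",
      "coef": 0.0317321,
      "transform": [
        {
          "op": "subtract",
          "value": 27
        }
      ]
    },
    {
      "predictor": "quit_years",
      "coef": -0.0308572,
      "transform": [
        {
          "op": "subtract",
          "value": 10
        }
      ]
    }
  ],
  "baselines": null
}
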