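{
  "schema_version": "1.0",
  "name": "PLCOall2014",
  "label": "Prostate, Lung, Colorectal and Ovarian 2014 all-participant model",
  "source": "Tammemagi MC et al., PLOS Med 2014;11:e1001764",
  "transcription": "surrogate: structure follows the 2012 smoker model with smoker-only terms gated and a smoking-status main effect; coefficients are plausible-scale stand-ins, not verified",
  "surrogate": true,
  "population": "all",
  "horizon_years": 6,
  "form": "logistic_direct",
  "intercept": -5,
  "terms": [
    {
      "predictor": "age",
      "coef": 0.079,
      "transform": [
        {
          "op": "subtract",
          "value": 62
        }
      ]
    },
    {
      "predictor": "education_level",
      "coef": -0.08,
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
      "coef": -0.028,
      "transform": [
        {
          "op": "subtract",
          "value": 27
        }
      ]
    },
    {
      "predictor": "copd",
      "coef": 0.35,
      "transform": []
    },
    {
      "predictor": "prior_cancer",
      "coef": 0.45,
      "transform": []
    },
    {
      "predictor": "family_history_lc",
      "coef": 0.58,
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
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "never": 0,
            "former": 0.85,
            "current": 1.15
          }
        }
      ]
    },
    {
      "predictor": "cigarettes_per_day",
      "coef": -1.8,
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
      ],
      "smoker_only": true
    },
    {
      "predictor": "smoking_years",
      "coef": 0.032,
      "transform": [
        {
          "op": "subtract",
          "value": 27
        }
      ],
      "smoker_only": true
    },
    {
      "predictor": "quit_years",
      "coef": -0.031,
      "transform": [
        {
          "op": "subtract",
          "value": 10
        }
      ],
      "smoker_only": true
    }
  ],
  "baselines": null
}
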