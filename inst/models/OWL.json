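{
  "schema_version": "1.0",
  "name": "OWL",
  "label": "Optimized early Warning model for Lung cancer risk",
  "source": "OWL model publication (gradient-boosting original)",
  "transcription": "surrogate: the original is a trained XGBoost model whose weights are out of scope; this is a documented logistic surrogate over the same predictor set with plausible effect directions",
  "surrogate": true,
  "population": "all",
  "horizon_years": 6,
  "form": "logistic_direct",
  "intercept": -5.6,
  "terms": [
    {
      "predictor": "age",
      "coef": 0.075,
      "transform": [
        {
          "op": "subtract",
          "value": 60
        }
      ]
    },
    {
      "predictor": "sex",
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "male": 0.35,
            "female": 0
          }
        }
      ]
    },
    {
      "predictor": "education_level",
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "middle_school_or_below": 0.15,
            "high_school": 0,
            "college_or_above": -0.1
          }
        }
      ]
    },
    {
      "predictor": "bmi",
      "coef": -0.03,
      "transform": [
        {
          "op": "subtract",
          "value": 24
        }
      ]
    },
    {
      "predictor": "family_history_lc",
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "none": 0,
            "first_degree": 0.6
          }
        }
      ]
    },
    {
      "predictor": "chronic_bronchitis",
      "coef": 0.3,
      "transform": []
    },
    {
      "predictor": "emphysema",
      "coef": 0.35,
      "transform": []
    },
    {
      "predictor": "copd",
      "coef": 0.45,
      "transform": []
    },
    {
      "predictor": "diabetes",
      "coef": 0.1,
      "transform": []
    },
    {
      "predictor": "smoking_status",
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "never": 0,
            "former": 0.5,
            "current": 0.8
          }
        }
      ]
    },
    {
      "predictor": "pack_years",
      "coef": 0.012,
      "transform": [
        {
          "op": "truncate",
          "lo": 0,
          "hi": 100
        }
      ],
      "smoker_only": true
    },
    {
      "predictor": "smoking_years",
      "coef": 0.01,
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
      "coef": -0.02,
      "transform": [],
      "smoker_only": true
    },
    {
      "predictor": "cigarettes_per_day",
      "coef": 0.005,
      "transform": [
        {
          "op": "subtract",
          "value": 16
        }
      ],
      "smoker_only": true
    },
    {
      "predictor": "age_started",
      "coef": -0.01,
      "transform": [
        {
          "op": "subtract",
          "value": 22
        }
      ],
      "smoker_only": true
    }
  ],
  "baselines": null
}
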