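{
  "schema_version": "1.0",
  "name": "LCRS",
  "label": "Lung Cancer Risk Score (Guangzhou development cohort)",
  "source": "LCRS original publication (Chinese cohort)",
  "transcription": "surrogate: binned scores with plausible magnitudes",
  "surrogate": true,
  "population": "all",
  "horizon_years": 6,
  "form": "cox_baseline",
  "intercept": 0,
  "terms": [
    {
      "predictor": "age",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [50, 55, 60, 65, 70, 75],
          "values": [0, 0.3, 0.6, 0.9, 1.15, 1.35, 1.5]
        }
      ]
    },
    {
      "predictor": "bmi",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [18.5, 24],
          "values": [0.2, 0, -0.1]
        }
      ]
    },
    {
      "predictor": "height",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [150, 155, 160],
          "values": [0.05, 0, 0, -0.05]
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
            "middle_school_or_below": 0.1,
            "high_school": 0,
            "college_or_above": -0.05
          }
        }
      ]
    },
    {
      "predictor": "physical_activity_minutes_per_week",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": 30,
          "values": [0.1, 0]
        }
      ]
    },
    {
      "predictor": "physical_activity_sessions_per_week",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": 3,
          "values": [0.1, 0]
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
            "first_degree": 0.55
          }
        }
      ]
    },
    {
      "predictor": "prior_cancer",
      "coef": 0.3,
      "transform": []
    },
    {
      "predictor": "chronic_bronchitis",
      "coef": 0.25,
      "transform": []
    },
    {
      "predictor": "emphysema",
      "coef": 0.3,
      "transform": []
    },
    {
      "predictor": "copd",
      "coef": 0.4,
      "transform": []
    },
    {
      "predictor": "cough",
      "coef": 0.2,
      "transform": []
    },
    {
      "predictor": "inhale_to_lungs",
      "coef": 0.15,
      "transform": [],
      "smoker_only": true
    },
    {
      "predictor": "smoking_years",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [10, 20, 30, 40, 50, 60],
          "values": [0.1, 0.25, 0.45, 0.65, 0.85, 1, 1.1]
        }
      ],
      "smoker_only": true
    },
    {
      "predictor": "smoking_status",
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "never": 0,
            "former": 0.2,
            "current": 0.4
          }
        }
      ]
    },
    {
      "predictor": "cigarettes_per_day",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [10, 15, 20, 25, 30, 35],
          "values": [0.05, 0.15, 0.25, 0.35, 0.4, 0.45, 0.5]
        }
      ],
      "smoker_only": true
    }
  ],
  "baselines": {
    "s0": 0.9955
  }
}
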