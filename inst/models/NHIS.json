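{
  "schema_version": "1.0",
  "name": "NHIS",
  "label": "Korean National Health Insurance Service model",
  "source": "NHIS lung cancer model publication (Korean cohort)",
  "transcription": "surrogate: plausible-scale coefficients, not verified",
  "surrogate": true,
  "population": "ever_only",
  "horizon_years": 6.6,
  "form": "cox_baseline",
  "intercept": 0,
  "terms": [
    {
      "predictor": "age",
      "coef": 0.06,
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
            "male": 0.3,
            "female": 0
          }
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
          "values": [0.25, 0, -0.1]
        }
      ]
    },
    {
      "predictor": "alcohol_days_per_week",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": 5,
          "values": [0, 0.05]
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
      "predictor": "emphysema",
      "coef": 0.35,
      "transform": []
    },
    {
      "predictor": "interstitial_lung_disease",
      "coef": 0.2,
      "transform": []
    },
    {
      "predictor": "copd",
      "coef": 0.4,
      "transform": []
    },
    {
      "predictor": "pack_years",
      "coef": 0.011,
      "transform": [
        {
          "op": "truncate",
          "lo": 0,
          "hi": 120
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
            "former": 0,
            "current": 0.3
          }
        }
      ]
    }
  ],
  "baselines": {
    "s0": 0.9935
  }
}
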