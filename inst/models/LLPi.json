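{
  "schema_version": "1.0",
  "name": "LLPi",
  "label": "Liverpool Lung Project incidence model",
  "source": "Marcus MW et al., Cancer Prev Res 2015;8:570-575",
  "transcription": "surrogate: plausible-scale coefficients, not verified",
  "surrogate": true,
  "population": "all",
  "horizon_years": 8.7,
  "form": "cox_baseline",
  "intercept": 0,
  "terms": [
    {
      "predictor": "age",
      "coef": 0.07,
      "transform": [
        {
          "op": "subtract",
          "value": 62
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
      "coef": 0.4,
      "transform": []
    },
    {
      "predictor": "copd",
      "coef": 0.45,
      "transform": []
    },
    {
      "predictor": "smoking_years",
      "coef": 0.022,
      "transform": [
        {
          "op": "truncate",
          "lo": 0,
          "hi": 70
        }
      ],
      "smoker_only": true
    }
  ],
  "baselines": {
    "s0": 0.9915
  }
}
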