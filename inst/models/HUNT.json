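{
  "schema_version": "1.0",
  "name": "HUNT",
  "label": "HUNT Lung Cancer Model (Nord-Trondelag Health Study)",
  "source": "Markaki M et al., EBioMedicine 2018;31:36-46",
  "transcription": "surrogate: plausible-scale coefficients, not verified",
  "surrogate": true,
  "population": "ever_only",
  "horizon_years": 6,
  "form": "cox_baseline",
  "intercept": 0,
  "terms": [
    {
      "predictor": "age",
      "coef": 0.065,
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
            "male": 0.25,
            "female": 0
          }
        }
      ]
    },
    {
      "predictor": "bmi",
      "coef": -0.035,
      "transform": [
        {
          "op": "subtract",
          "value": 25
        }
      ]
    },
    {
      "predictor": "cough",
      "coef": 0.45,
      "transform": []
    },
    {
      "predictor": "secondhand_smoke_hours_per_day",
      "coef": 0.05,
      "transform": []
    },
    {
      "predictor": "pack_years",
      "coef": 0.012,
      "transform": [
        {
          "op": "truncate",
          "lo": 0,
          "hi": 100
        },
        {
          "op": "subtract",
          "value": 25
        }
      ]
    },
    {
      "predictor": "quit_years",
      "coef": -0.027,
      "transform": []
    },
    {
      "predictor": "cigarettes_per_day",
      "coef": 0.012,
      "transform": [
        {
          "op": "subtract",
          "value": 15
        }
      ]
    }
  ],
  "baselines": {
    "s0": 0.993
  }
}
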