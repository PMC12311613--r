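{
  "schema_version": "1.0",
  "name": "LLPv3",
  "label": "Liverpool Lung Project risk model, version 3",
  "source": "Field JK et al. (LLP recalibration); see version 2 source",
  "transcription": "surrogate: version-2 structure with the baseline incidence recalibrated downwards and a flattened age gradient, mirroring the published recalibration direction",
  "surrogate": true,
  "population": "all",
  "horizon_years": 5,
  "form": "rr_times_incidence",
  "intercept": 0,
  "terms": [
    {
      "predictor": "smoking_years",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [20, 40, 60],
          "values": [0.77, 1.452, 2.109, 2.303]
        }
      ],
      "smoker_only": true
    },
    {
      "predictor": "family_history_lc",
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "none": 0,
            "first_degree": 0.513
          }
        }
      ]
    },
    {
      "predictor": "asbestos_exposure",
      "coef": 0.637,
      "transform": []
    },
    {
      "predictor": "prior_cancer",
      "coef": 0.673,
      "transform": []
    },
    {
      "predictor": "copd",
      "coef": 0.432,
      "transform": []
    }
  ],
  "baselines": {
    "incidence": [
      {
        "sex": "male",
        "age_lo": 45,
        "age_hi": 49,
        "risk": 0.0017081
      },
      {
        "sex": "male",
        "age_lo": 50,
        "age_hi": 54,
        "risk": 0.0019313
      },
      {
        "sex": "male",
        "age_lo": 55,
        "age_hi": 59,
        "risk": 0.0022661
      },
      {
        "sex": "male",
        "age_lo": 60,
        "age_hi": 64,
        "risk": 0.0028241
      },
      {
        "sex": "male",
        "age_lo": 65,
        "age_hi": 69,
        "risk": 0.0035681
      },
      {
        "sex": "male",
        "age_lo": 70,
        "age_hi": 74,
        "risk": 0.0043121
      },
      {
        "sex": "male",
        "age_lo": 75,
        "age_hi": 79,
        "risk": 0.0048701
      },
      {
        "sex": "male",
        "age_lo": 80,
        "age_hi": 110,
        "risk": 0.0052421
      },
      {
        "sex": "female",
        "age_lo": 45,
        "age_hi": 49,
        "risk": 0.001281075
      },
      {
        "sex": "female",
        "age_lo": 50,
        "age_hi": 54,
        "risk": 0.001448475
      },
      {
        "sex": "female",
        "age_lo": 55,
        "age_hi": 59,
        "risk": 0.001699575
      },
      {
        "sex": "female",
        "age_lo": 60,
        "age_hi": 64,
        "risk": 0.002118075
      },
      {
        "sex": "female",
        "age_lo": 65,
        "age_hi": 69,
        "risk": 0.002676075
      },
      {
        "sex": "female",
        "age_lo": 70,
        "age_hi": 74,
        "risk": 0.003234075
      },
      {
        "sex": "female",
        "age_lo": 75,
        "age_hi": 79,
        "risk": 0.003652575
      },
      {
        "sex": "female",
        "age_lo": 80,
        "age_hi": 110,
        "risk": 0.003931575
      }
    ]
  }
}
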