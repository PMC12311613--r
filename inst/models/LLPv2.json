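{
  "schema_version": "1.0",
  "name": "LLPv2",
  "label": "Liverpool Lung Project risk model, version 2",
  "source": "Cassidy A et al., Br J Cancer 2008;98:270-276",
  "transcription": "surrogate: odds ratios carry the published magnitudes approximately; the age-sex baseline incidence table is a synthetic stand-in with a folded normalisation constant",
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
        "risk": 0.001
      },
      {
        "sex": "male",
        "age_lo": 50,
        "age_hi": 54,
        "risk": 0.0016
      },
      {
        "sex": "male",
        "age_lo": 55,
        "age_hi": 59,
        "risk": 0.0025
      },
      {
        "sex": "male",
        "age_lo": 60,
        "age_hi": 64,
        "risk": 0.004
      },
      {
        "sex": "male",
        "age_lo": 65,
        "age_hi": 69,
        "risk": 0.006
      },
      {
        "sex": "male",
        "age_lo": 70,
        "age_hi": 74,
        "risk": 0.008
      },
      {
        "sex": "male",
        "age_lo": 75,
        "age_hi": 79,
        "risk": 0.0095
      },
      {
        "sex": "male",
        "age_lo": 80,
        "age_hi": 110,
        "risk": 0.0105
      },
      {
        "sex": "female",
        "age_lo": 45,
        "age_hi": 49,
        "risk": 0.00075
      },
      {
        "sex": "female",
        "age_lo": 50,
        "age_hi": 54,
        "risk": 0.0012
      },
      {
        "sex": "female",
        "age_lo": 55,
        "age_hi": 59,
        "risk": 0.001875
      },
      {
        "sex": "female",
        "age_lo": 60,
        "age_hi": 64,
        "risk": 0.003
      },
      {
        "sex": "female",
        "age_lo": 65,
        "age_hi": 69,
        "risk": 0.0045
      },
      {
        "sex": "female",
        "age_lo": 70,
        "age_hi": 74,
        "risk": 0.006
      },
      {
        "sex": "female",
        "age_lo": 75,
        "age_hi": 79,
        "risk": 0.007125
      },
      {
        "sex": "female",
        "age_lo": 80,
        "age_hi": 110,
        "risk": 0.007875
      }
    ]
  }
}
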