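{
  "schema_version": "1.0",
  "name": "Bach",
  "label": "Bach model (CARET-derived annual risk recursion)",
  "source": "Bach PB et al., J Natl Cancer Inst 2003;95:470-478",
  "transcription": "surrogate: annual-recursion structure with synthetic baseline hazard tables and binned covariate effects of plausible magnitude",
  "surrogate": true,
  "population": "ever_only",
  "horizon_years": 10,
  "form": "annual_recursion",
  "intercept": 0,
  "terms": [
    {
      "predictor": "cigarettes_per_day",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [10, 15, 20, 25, 30, 35],
          "values": [-0.45, -0.2, -0.05, 0, 0.1, 0.2, 0.3]
        }
      ]
    },
    {
      "predictor": "smoking_years",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [10, 20, 30, 40, 50, 60],
          "values": [-1.2, -0.8, -0.4, -0.1, 0.15, 0.35, 0.5]
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
            "former": -0.35,
            "current": 0
          }
        }
      ]
    },
    {
      "predictor": "asbestos_exposure",
      "coef": 0.25,
      "transform": []
    }
  ],
  "baselines": {
    "lc_hazard": [
      {
        "sex": "male",
        "age_lo": 45,
        "age_hi": 49,
        "hazard": 0.0004
      },
      {
        "sex": "male",
        "age_lo": 50,
        "age_hi": 54,
        "hazard": 0.0007
      },
      {
        "sex": "male",
        "age_lo": 55,
        "age_hi": 59,
        "hazard": 0.0012
      },
      {
        "sex": "male",
        "age_lo": 60,
        "age_hi": 64,
        "hazard": 0.0019
      },
      {
        "sex": "male",
        "age_lo": 65,
        "age_hi": 69,
        "hazard": 0.0028
      },
      {
        "sex": "male",
        "age_lo": 70,
        "age_hi": 74,
        "hazard": 0.0038
      },
      {
        "sex": "male",
        "age_lo": 75,
        "age_hi": 79,
        "hazard": 0.0048
      },
      {
        "sex": "male",
        "age_lo": 80,
        "age_hi": 110,
        "hazard": 0.0055
      },
      {
        "sex": "female",
        "age_lo": 45,
        "age_hi": 49,
        "hazard": 0.00028
      },
      {
        "sex": "female",
        "age_lo": 50,
        "age_hi": 54,
        "hazard": 0.00049
      },
      {
        "sex": "female",
        "age_lo": 55,
        "age_hi": 59,
        "hazard": 0.00084
      },
      {
        "sex": "female",
        "age_lo": 60,
        "age_hi": 64,
        "hazard": 0.00133
      },
      {
        "sex": "female",
        "age_lo": 65,
        "age_hi": 69,
        "hazard": 0.00196
      },
      {
        "sex": "female",
        "age_lo": 70,
        "age_hi": 74,
        "hazard": 0.00266
      },
      {
        "sex": "female",
        "age_lo": 75,
        "age_hi": 79,
        "hazard": 0.00336
      },
      {
        "sex": "female",
        "age_lo": 80,
        "age_hi": 110,
        "hazard": 0.00385
      }
    ],
    "mortality_hazard": [
      {
        "sex": "any",
        "age_lo": 45,
        "age_hi": 49,
        "hazard": 0.003
      },
      {
        "sex": "any",
        "age_lo": 50,
        "age_hi": 54,
        "hazard": 0.005
      },
      {
        "sex": "any",
        "age_lo": 55,
        "age_hi": 59,
        "hazard": 0.008
      },
      {
        "sex": "any",
        "age_lo": 60,
        "age_hi": 64,
        "hazard": 0.013
      },
      {
        "sex": "any",
        "age_lo": 65,
        "age_hi": 69,
        "hazard": 0.021
      },
      {
        "sex": "any",
        "age_lo": 70,
        "age_hi": 74,
        "hazard": 0.034
      },
      {
        "sex": "any",
        "age_lo": 75,
        "age_hi": 79,
        "hazard": 0.055
      },
      {
        "sex": "any",
        "age_lo": 80,
        "age_hi": 110,
        "hazard": 0.09
      }
    ]
  }
}
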