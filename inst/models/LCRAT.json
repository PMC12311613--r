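{
  "schema_version": "1.0",
  "name": "LCRAT",
  "label": "Lung Cancer Risk Assessment Tool",
  "source": "Katki HA et al., JAMA 2016;315:2300-2311",
  "transcription": "surrogate: annual-recursion structure with synthetic baseline hazard tables and plausible-scale covariate effects",
  "surrogate": true,
  "population": "ever_only",
  "horizon_years": 5,
  "form": "annual_recursion",
  "intercept": 0,
  "terms": [
    {
      "predictor": "education_level",
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "middle_school_or_below": 0.08,
            "high_school": -0.02,
            "college_or_above": -0.15
          }
        }
      ]
    },
    {
      "predictor": "bmi",
      "coef": -0.02,
      "transform": [
        {
          "op": "subtract",
          "value": 23
        }
      ]
    },
    {
      "predictor": "emphysema",
      "coef": 0.4,
      "transform": []
    },
    {
      "predictor": "family_history_lc",
      "coef": 1,
      "transform": [
        {
          "op": "map",
          "levels": {
            "none": 0,
            "first_degree": 0.45
          }
        }
      ]
    },
    {
      "predictor": "smoking_years",
      "coef": 0.025,
      "transform": [
        {
          "op": "subtract",
          "value": 35
        }
      ]
    },
    {
      "predictor": "quit_years",
      "coef": -0.03,
      "transform": [
        {
          "op": "subtract",
          "value": 5
        }
      ]
    },
    {
      "predictor": "pack_years",
      "coef": 0.35,
      "transform": [
        {
          "op": "log",
          "offset": 1
        },
        {
          "op": "subtract",
          "value": 3.434
        }
      ]
    },
    {
      "predictor": "cigarettes_per_day",
      "coef": 0.005,
      "transform": [
        {
          "op": "subtract",
          "value": 18
        }
      ]
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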