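{
  "schema_version": "1.0",
  "name": "Pittsburgh",
  "label": "Pittsburgh Predictor",
  "source": "Wilson DO, Weissfeld J, Lung Cancer 2015;89:31-37",
  "transcription": "surrogate: binned scores with plausible magnitudes",
  "surrogate": true,
  "population": "ever_only",
  "horizon_years": 6,
  "form": "logistic_direct",
  "intercept": -5.8,
  "terms": [
    {
      "predictor": "age",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [50, 55, 60, 65, 70, 75, 80],
          "values": [0, 0.35, 0.7, 1, 1.3, 1.55, 1.75, 1.9]
        }
      ]
    },
    {
      "predictor": "smoking_years",
      "coef": 1,
      "transform": [
        {
          "op": "bin",
          "breaks": [10, 20, 30, 40, 50],
          "values": [0, 0.3, 0.6, 0.9, 1.15, 1.35]
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
            "current": 0.35
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
          "breaks": [10, 20, 30],
          "values": [0, 0.25, 0.45, 0.6]
        }
      ]
    }
  ],
  "baselines": null
}
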