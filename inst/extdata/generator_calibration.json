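{
  "comment": "Calibration of the synthetic-cohort ground truth. Marginal class frequencies come from the packaged stratified-count fixture; the anchors below pin down the conditional dependencies that the margins alone leave free. Remaining conditional columns are solved from the margins in code, so every marginal is matched by construction.",
  "learned_arcs": [
    ["sex", "smoking"],
    ["sex", "alcoholism"],
    ["sex", "bmi"],
    ["bmi", "epicardial_fat"],
    ["osa", "af_type"],
    ["af_type", "la_volume"]
  ],
  "anchors": {
    "smoking_given_male": 0.36,
    "alcoholism_given_male": 0.075,
    "bmi_given_male": [0.26, 0.5, 0.24],
    "persistent_given_osa_true": 0.4,
    "la_volume_given_persistent": [0.15, 0.33, 0.52],
    "epicardial_fat_given_bmi_normal": [0.6, 0.3, 0.1],
    "epicardial_fat_given_bmi_obese": [0.1, 0.3, 0.6]
  },
  "logistic_effects": {
    "diabetes": {
      "age": [-0.7, 0.0, 0.5],
      "bmi": [-0.5, 0.0, 0.8]
    },
    "hbp": {
      "age": [-1.0, 0.0, 0.8],
      "bmi": [-0.4, 0.0, 0.7]
    },
    "osa": {
      "bmi": [-1.0, 0.0, 1.3]
    }
  }
}
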