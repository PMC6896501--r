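{
  "meta": {
    "label": "reconstructed synthetic default bundle (not transcribed from any registry)",
    "index_year": 2017,
    "description": "Natural-history block calibrated to synthetic Austrian-style incidence/stage/cumulative-mortality targets; life table is a synthetic Gompertz-Makeham table; survival table synthetic."
  },
  "files": {
    "life_table": "default_parameters_life_table.csv",
    "crc_survival": "default_parameters_crc_survival.csv"
  },
  "natural_history": {
    "onset_base": 0.0409494943484611,
    "onset_slope": 0.0999999990887142,
    "onset_cap": 0.05,
    "adenoma_to_advanced": 0.0644033243133604,
    "advanced_to_preclinical": 0.0100000547599268,
    "stage_progression": [0.100000002405124, 0.661955577237187, 0.74761840494324],
    "symptomatic_detection": [0.0210956613638832, 0.223349538048393, 0.454892890896709, 0.94999999277761],
    "age_constant": true
  },
  "tests": {
    "FIT": {
      "sensitivity_adenoma": 0.076,
      "sensitivity_advanced_adenoma": 0.367,
      "sensitivity_crc": 0.872,
      "specificity": 0.928
    },
    "gFOBT": {
      "sensitivity_adenoma": 0.0945,
      "sensitivity_advanced_adenoma": 0.239,
      "sensitivity_crc": 0.722,
      "specificity": 0.9
    },
    "colonoscopy": {
      "sensitivity_adenoma": 0.69,
      "sensitivity_advanced_adenoma": 0.867,
      "sensitivity_crc": 0.947,
      "specificity": 1
    }
  },
  "hazard_ratios": {
    "1": 0.77,
    "2": 0.8,
    "3": 0.84,
    "4": 0.9
  },
  "costs": {
    "colonoscopy": 228,
    "polypectomy": 64,
    "gfobt_test": 37,
    "fit_test": 41,
    "staging": 461,
    "inpatient_by_stage": [13831, 18699, 19038, 24059],
    "medication_uicc_iv": 12433,
    "followup_by_year": [552, 367, 349, 419, 237],
    "followup_longterm_per_5y": 228,
    "program_cost": {
      "colonoscopy_program": 1950353,
      "stool_program": 4118142
    },
    "program_divisor": 2000000,
    "complication_surgical": 23258,
    "complication_inpatient": 5250,
    "end_of_life": {
      "I_II": 55530,
      "III": 36492
    },
    "index_year": 2017
  },
  "complications": {
    "per_colonoscopy_admission": 0.000375,
    "surgical_fraction": 0.2
  }
}
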