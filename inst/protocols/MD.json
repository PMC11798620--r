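{
  "id": "MD",
  "label": "Multi-principle point system with age and pregnancy weighting, FCFS tie-break (MD)",
  "sofa_exclusion": {"comparator": ">", "cutoff": 14},
  "excluded_comorbidities": ["esrd", "ms_late_stage", "hf_nyha_iv"],
  "sofa_bands": [
    {"min": 0, "max": 5, "points": 1},
    {"min": 6, "max": 9, "points": 2},
    {"min": 10, "max": 14, "points": 3}
  ],
  "comorbidity_points": {
    "severity": {"none": 0, "minor": 0, "severe_life_limiting": 0},
    "overrides": {}
  },
  "age_bands": [
    {"min": 18, "max": 49, "points": 0},
    {"min": 50, "max": 130, "points": 1}
  ],
  "pregnancy_modifier": -2,
  "frontline_policy": "ignored",
  "qualification_sofa_cutoff": null,
  "tiebreak_chain": ["younger_age", "fcfs"]
}
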