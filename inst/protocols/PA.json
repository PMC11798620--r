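{
  "id": "PA",
  "label": "Multi-principle point system with comorbidity weighting, age/frontline tie-breaks then lottery (PA)",
  "sofa_exclusion": null,
  "excluded_comorbidities": [],
  "sofa_bands": [
    {"min": 0, "max": 5, "points": 1},
    {"min": 6, "max": 8, "points": 2},
    {"min": 9, "max": 11, "points": 3},
    {"min": 12, "max": 24, "points": 4}
  ],
  "comorbidity_points": {
    "severity": {"none": 0, "minor": 0, "severe_life_limiting": 4},
    "overrides": {"dementia": 0}
  },
  "age_bands": null,
  "pregnancy_modifier": null,
  "frontline_policy": "tiebreak_only",
  "qualification_sofa_cutoff": null,
  "tiebreak_chain": ["younger_age", "frontline", "lottery"]
}
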