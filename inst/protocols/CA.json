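{
  "id": "CA",
  "label": "Multi-principle point system with age and pregnancy weighting, frontline exemption, lottery tie-break (CA)",
  "sofa_exclusion": null,
  "excluded_comorbidities": [],
  "sofa_bands": [
    {"min": 0, "max": 5, "points": 1},
    {"min": 6, "max": 8, "points": 2},
    {"min": 9, "max": 11, "points": 3},
    {"min": 12, "max": 24, "points": 4}
  ],
  "comorbidity_points": {
    "severity": {"none": 0, "minor": 0, "severe_life_limiting": 0},
    "overrides": {}
  },
  "age_bands": [
    {"min": 18, "max": 49, "points": 0},
    {"min": 50, "max": 69, "points": 1},
    {"min": 70, "max": 84, "points": 2},
    {"min": 85, "max": 130, "points": 3}
  ],
  "pregnancy_modifier": -3,
  "frontline_policy": "exemption",
  "qualification_sofa_cutoff": null,
  "tiebreak_chain": ["lottery"]
}
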