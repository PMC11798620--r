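{
  "id": "NY",
  "label": "SOFA band priority groups with severity exclusion, FCFS tie-break (NY)",
  "sofa_exclusion": {"comparator": ">", "cutoff": 11},
  "excluded_comorbidities": [],
  "sofa_bands": [
    {"min": 0, "max": 7, "points": 1},
    {"min": 8, "max": 11, "points": 2}
  ],
  "comorbidity_points": {
    "severity": {"none": 0, "minor": 0, "severe_life_limiting": 0},
    "overrides": {}
  },
  "age_bands": null,
  "pregnancy_modifier": null,
  "frontline_policy": "ignored",
  "qualification_sofa_cutoff": null,
  "tiebreak_chain": ["fcfs"]
}
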