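{
  "id": "NE",
  "label": "SOFA qualification cutoff without scoring or tie-breaking (NE)",
  "sofa_exclusion": null,
  "excluded_comorbidities": [],
  "sofa_bands": null,
  "comorbidity_points": {
    "severity": {"none": 0, "minor": 0, "severe_life_limiting": 0},
    "overrides": {}
  },
  "age_bands": null,
  "pregnancy_modifier": null,
  "frontline_policy": "ignored",
  "qualification_sofa_cutoff": 10,
  "tiebreak_chain": []
}
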