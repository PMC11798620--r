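{
  "id": "FL",
  "label": "Raw-SOFA ranking with comorbidity and severity exclusions, FCFS tie-break (FL)",
  "sofa_exclusion": {"comparator": ">=", "cutoff": 10},
  "excluded_comorbidities": ["esrd", "metastatic_cancer", "ms_late_stage", "hf_nyha_iv"],
  "sofa_bands": "raw",
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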