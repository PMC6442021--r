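{
  "name": "ICON5 (five-arm two-stage design; interim omega and hazard ratios not part of the published specification, values here are conventional defaults)",
  "n_comparisons": 4,
  "allocation": 1,
  "alpha": [0.064, 0.025],
  "omega": [0.95, 0.98],
  "outcomes": {
    "intermediate": {"name": "PFS", "hr_null": 1, "hr_alt": 0.75},
    "definitive":   {"name": "OS",  "hr_null": 1, "hr_alt": 0.75}
  },
  "binding": false,
  "stopping_rule": "separate",
  "efficacy": {"kind": "none"}
}
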