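{
  "name": "STAMPEDE (original six-arm four-stage design)",
  "n_comparisons": 5,
  "allocation": 0.5,
  "alpha": [0.5, 0.25, 0.1, 0.025],
  "omega": [0.95, 0.95, 0.95, 0.90],
  "outcomes": {
    "intermediate": {"name": "FFS", "hr_null": 1, "hr_alt": 0.75},
    "definitive":   {"name": "OS",  "hr_null": 1, "hr_alt": 0.75}
  },
  "binding": false,
  "stopping_rule": "separate",
  "control_events": [113, 216, 334, 403],
  "efficacy": {"kind": "none"}
}
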