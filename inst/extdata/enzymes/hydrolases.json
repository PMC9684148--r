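{
  "chitinosanase": {
    "type": "hydrolase", "mode": "absolute",
    "allowed": {"-2": ["D"], "-1": ["A"]},
    "required": ["-2", "-1", "+1"]
  },
  "ChiB": {
    "type": "hydrolase", "mode": "absolute",
    "allowed": {"-1": ["A"]},
    "required": ["-2", "-1", "+1"]
  },
  "ChT": {
    "type": "hydrolase", "mode": "absolute",
    "allowed": {"-1": ["A"]},
    "required": ["-2", "-1", "+1"]
  },
  "Csn174": {
    "type": "hydrolase", "mode": "absolute",
    "allowed": {"-1": ["D"], "+1": ["D"]},
    "required": ["-2", "-1", "+1", "+2"]
  },
  "lysozyme": {
    "type": "hydrolase", "mode": "absolute",
    "allowed": {"-2": ["A"], "-1": ["A"], "+1": ["A"]},
    "required": ["-3", "-2", "-1", "+1", "+2"]
  }
}
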