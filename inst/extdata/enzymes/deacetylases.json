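{
  "uniform": {
    "type": "deacetylase", "mode": "reverse", "end_weight": 1, "k": 1,
    "weights": {
      "-2": {"A": 1, "D": 1},
      "-1": {"A": 1, "D": 1},
      "+1": {"A": 1, "D": 1}
    }
  },
  "AnCDA": {
    "type": "deacetylase", "mode": "reverse", "end_weight": 1, "k": 1,
    "weights": {
      "-2": {"A": 2, "D": 1},
      "-1": {"A": 10, "D": 1},
      "+1": {"A": 2, "D": 1}
    }
  },
  "PesCDA": {
    "type": "deacetylase", "mode": "reverse", "end_weight": 1, "k": 1,
    "weights": {
      "-2": {"A": 3, "D": 1},
      "-1": {"A": 10, "D": 1},
      "+1": {"A": 2, "D": 1}
    }
  },
  "CnCDA4": {
    "type": "deacetylase", "mode": "reverse", "end_weight": 1, "k": 1,
    "weights": {
      "-2": {"A": 1, "D": 1},
      "-1": {"A": 1, "D": 10},
      "+1": {"A": 1, "D": 1}
    }
  },
  "PgtCDA": {
    "type": "deacetylase", "mode": "reverse", "end_weight": 1, "k": 1,
    "weights": {
      "-2": {"A": 1, "D": 1},
      "-1": {"A": 1, "D": 2},
      "+1": {"A": 1, "D": 1}
    }
  }
}
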