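{
  "name": "HNcoCACB",
  "dimensions": [
    {"label": "H",     "classes": ["H"],        "position": 0},
    {"label": "N",     "classes": ["N"],        "position": 0},
    {"label": "CA/CB", "classes": ["CA", "CB"], "position": -1}
  ],
  "comparable_dims": [1, 2]
}
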