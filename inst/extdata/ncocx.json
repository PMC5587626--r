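{
  "name": "NCOCX",
  "dimensions": [
    {"label": "N",  "classes": ["N"],  "position": 0},
    {"label": "CO", "classes": ["CO"], "position": -1},
    {"label": "CX", "classes": ["CX"], "position": -1}
  ],
  "comparable_dims": [1, 2]
}
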