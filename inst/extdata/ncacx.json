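{
  "name": "NCACX",
  "dimensions": [
    {"label": "N",  "classes": ["N"],  "position": 0},
    {"label": "CA", "classes": ["CA"], "position": 0},
    {"label": "CX", "classes": ["CX"], "position": 0}
  ],
  "comparable_dims": [1, 2]
}
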