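{
  "system": "CAPRA",
  "version": "UCSF pre-treatment CAPRA (Cooperberg et al., J Urol 2005)",
  "notes": "Gleason pattern points mapped to grade groups: GG1 (no pattern 4/5) = 0, GG2 (secondary 4) = 1, GG3-5 (primary 4/5) = 3.",
  "range": [0, 10],
  "points": {
    "psa": [
      {"max": 6, "points": 0},
      {"max": 10, "points": 1},
      {"max": 20, "points": 2},
      {"max": 30, "points": 3},
      {"max": null, "points": 4}
    ],
    "gg_nb": {"1": 0, "2": 1, "3": 3, "4": 3, "5": 3},
    "ct": {"1": 0, "2": 0, "3": 1, "4": 1},
    "ppb": [
      {"max": 33.999, "points": 0},
      {"max": null, "points": 1}
    ],
    "age": [
      {"max": 49.999, "points": 0},
      {"max": null, "points": 1}
    ]
  },
  "categories": [
    {"max": 2, "label": "low"},
    {"max": 5, "label": "intermediate"},
    {"max": null, "label": "high"}
  ]
}
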