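{
  "system": "CAPRA-S",
  "version": "UCSF post-surgical CAPRA-S (Cooperberg et al., Cancer 2011)",
  "notes": "Pathologic Gleason mapped to grade groups: GG1 (no pattern 4/5) = 0, GG2 (secondary 4/5) = 1, GG3-5 (primary 4/5) = 3. Lymph-node invasion defaults to negative when absent.",
  "range": [0, 12],
  "points": {
    "psa": [
      {"max": 6, "points": 0},
      {"max": 10, "points": 1},
      {"max": 20, "points": 2},
      {"max": null, "points": 3}
    ],
    "gg_rp": {"1": 0, "2": 1, "3": 3, "4": 3, "5": 3},
    "sm": {"0": 0, "1": 2},
    "svi": {"0": 0, "1": 2},
    "epe": {"0": 0, "1": 1},
    "ln": {"0": 0, "1": 1}
  },
  "categories": [
    {"max": 2, "label": "low"},
    {"max": 5, "label": "intermediate"},
    {"max": null, "label": "high"}
  ]
}
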