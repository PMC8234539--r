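{
  "system": "NCCN",
  "version": "three-tier localized prostate cancer risk groups (NCCN guidelines)",
  "notes": "low: cT1-T2a AND GG1 AND PSA < 10; high: cT3a or higher OR GG4-5 OR PSA > 20; otherwise intermediate. Clinical T is recorded at integer resolution here, so cT >= 3 maps to the high-risk criterion and cT <= 2 to the low-risk criterion.",
  "rules": {
    "low": {"ct_max": 2, "gg_nb_max": 1, "psa_max": 10},
    "high": {"ct_min": 3, "gg_nb_min": 4, "psa_min": 20}
  },
  "levels": ["low", "intermediate", "high"]
}
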