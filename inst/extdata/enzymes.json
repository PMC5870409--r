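[
  {"name": "DdeI",    "recognition": "CTNAG",      "cut_offset": 1},
  {"name": "XmnI",    "recognition": "GAANNNNTTC", "cut_offset": 5},
  {"name": "HindIII", "recognition": "AAGCTT",     "cut_offset": 1},
  {"name": "HincII",  "recognition": "GTYRAC",     "cut_offset": 3},
  {"name": "HinfI",   "recognition": "GANTC",      "cut_offset": 1}
]
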