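{
  "provenance": "SYNTHETIC rat IV two-compartment PK parameter sets for the synthetic-study generator (true rat PK lies in companion work outside this package's inputs). Magnitudes chosen for a 0.28 kg rat: clearances 2-3 L/h/kg, distribution volumes ~1-2 L/kg, terminal half-lives 1-2 h.",
  "units": { "cl": "L/h", "v1": "L", "q": "L/h", "v2": "L" },
  "models": {
    "remoxipride": { "type": "iv_2cmt", "cl": 0.56, "v1": 0.25, "q": 0.3, "v2": 0.35 },
    "paliperidone": { "type": "iv_2cmt", "cl": 0.84, "v1": 0.3, "q": 0.4, "v2": 0.6 },
    "risperidone": { "type": "iv_2cmt", "cl": 0.84, "v1": 0.3, "q": 0.4, "v2": 0.6 }
  }
}
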