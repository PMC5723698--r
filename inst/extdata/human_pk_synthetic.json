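{
  "provenance": "SYNTHETIC stand-in for the unavailable supplementary human PK table. Values are calibrated a priori to the descriptors the source states in its main text: remoxipride follows two-compartment IV kinetics with a terminal half-life of about 5 h and clinically observed exposure; OROS paliperidone follows a one-compartment model with sequential zero-/first-order absorption, zero-order release longer than 20 h, terminal half-life about 28 h, steady state near day 4. Not a transcription of any published table.",
  "units": {
    "cl": "L/h", "v1": "L", "q": "L/h", "v2": "L",
    "release_duration": "h", "ka": "1/h", "cl_over_f": "L/h", "v_over_f": "L"
  },
  "models": {
    "remoxipride": {
      "type": "iv_2cmt",
      "cl": 8, "v1": 40, "q": 15, "v2": 18,
      "note": "terminal half-life 5.3 h; oral clinical doses are simulated through this IV model, mirroring the source's approach"
    },
    "paliperidone": {
      "type": "oral_oros",
      "release_duration": 22, "ka": 0.5, "cl_over_f": 12, "v_over_f": 485,
      "note": "apparent terminal half-life 28.0 h"
    }
  }
}
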