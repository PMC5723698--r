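{
  "units": {
    "molecular_weight": "g/mol",
    "fraction_unbound": "dimensionless (0,1]",
    "ki_invitro_rat": "nmol/L",
    "ki_invitro_human": "nmol/L",
    "ki_invivo_rat": "nmol/L",
    "ec50_human": "nmol/L (unbound scale; published human estimates)",
    "emax": "dimensionless fold-increase"
  },
  "compounds": {
    "paliperidone": {
      "molecular_weight": 426.48,
      "fraction_unbound": 0.226,
      "ki_invitro_rat": 2.74,
      "ki_invitro_human": 2.08,
      "ki_invivo_rat": 11.1,
      "ec50_human": 276,
      "emax": 66,
      "note": "fraction_unbound = 1 - 0.774 protein binding; ec50_human = 0.276 umol/L derived cross-compound from the remoxipride human EC50"
    },
    "remoxipride": {
      "molecular_weight": 371.26,
      "fraction_unbound": 0.2,
      "ki_invitro_rat": 370.66,
      "ki_invitro_human": 165.75,
      "ki_invivo_rat": 113,
      "ec50_human": 22000,
      "emax": 66,
      "note": "fraction_unbound = 1 - 0.80 protein binding; ec50_human = 22 umol/L"
    },
    "risperidone": {
      "molecular_weight": 410.48,
      "fraction_unbound": 0.1,
      "ki_invitro_rat": 3.2,
      "ki_invitro_human": 3.2,
      "ki_invivo_rat": 10.0,
      "ec50_human": null,
      "emax": 66,
      "synthetic_placeholder": true,
      "note": "SYNTHETIC placeholder potencies (no published values available in the source tables); excluded from quantitative benchmarks"
    }
  }
}
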