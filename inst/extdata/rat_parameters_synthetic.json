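{
  "provenance": "SYNTHETIC stand-in for the unavailable supplementary rat estimates. Turnover rates are back-derived by inverting the allometric rule (multiplying the published translated human values 12.4/0.060/1.67 by (70/0.28)^0.25) so that translation reproduces the published human set exactly; ECu50 values are back-derived from RO50 = 56.3% and the published in vivo rat KIs (ECu50 = KI * 56.3/43.7 under competition-free occupancy); k_da, k_in0 and all risperidone potencies are synthetic choices documented in the methods vignette.",
  "units": {
    "r_form": "ng/mL/h", "k_base": "1/h", "k_out": "1/h", "emax": "dimensionless",
    "ecu50": "nmol/L", "k_in0": "ng/mL/h", "k_da": "1/h",
    "das0": "dimensionless", "ki": "nmol/L", "gamma": "dimensionless"
  },
  "sets": {
    "pp_rat_paliperidone": {
      "model": "pp", "species": "rat",
      "r_form": 49.306785183557139, "k_base": 0.23858121863011517,
      "k_out": 6.640510585204872, "emax": 66,
      "ecu50": 14.300457665903888, "gamma": 1, "pf": 0
    },
    "pp_rat_remoxipride": {
      "model": "pp", "species": "rat",
      "r_form": 49.306785183557139, "k_base": 0.23858121863011517,
      "k_out": 6.640510585204872, "emax": 66,
      "ecu50": 145.58123569794049, "gamma": 1, "pf": 0
    },
    "pp_rat_risperidone": {
      "model": "pp", "species": "rat",
      "r_form": 49.306785183557139, "k_base": 0.23858121863011517,
      "k_out": 6.640510585204872, "emax": 66,
      "ecu50": 12.0, "gamma": 1, "pf": 0,
      "synthetic_placeholder": true
    },
    "aai_rat_paliperidone": {
      "model": "aai", "species": "rat",
      "k_in0": 49.306785183557139, "k_out": 6.640510585204872,
      "k_da": 0.5, "das0": 10.9, "ki": 11.1, "gamma": 1
    },
    "aai_rat_remoxipride": {
      "model": "aai", "species": "rat",
      "k_in0": 49.306785183557139, "k_out": 6.640510585204872,
      "k_da": 0.5, "das0": 10.9, "ki": 113, "gamma": 1
    },
    "aai_rat_risperidone": {
      "model": "aai", "species": "rat",
      "k_in0": 49.306785183557139, "k_out": 6.640510585204872,
      "k_da": 0.5, "das0": 10.9, "ki": 10.0, "gamma": 1,
      "synthetic_placeholder": true
    }
  }
}
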