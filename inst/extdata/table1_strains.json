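[
  {
    "strain": "wild_type",
    "mu": 0.196,
    "qac": 7.88,
    "swap_fraction": 0,
    "pntab_present": true,
    "knockouts": []
  },
  {
    "strain": "dpntab",
    "mu": 0.191,
    "qac": 7.6,
    "swap_fraction": 0,
    "pntab_present": false,
    "knockouts": []
  },
  {
    "strain": "icd_nad",
    "mu": 0.135,
    "qac": 8.0,
    "swap_fraction": 1,
    "pntab_present": true,
    "knockouts": []
  },
  {
    "strain": "icd_nad_dpntab",
    "mu": 0.1203,
    "qac": 7.0,
    "swap_fraction": 1,
    "pntab_present": false,
    "knockouts": []
  }
]
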