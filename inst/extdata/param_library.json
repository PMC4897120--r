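[
  {
    "name": "asd_male",
    "k1": 0.12605,
    "k2": 0.030207,
    "m1": 17,
    "r": 1.0,
    "time_unit": "month",
    "note": "ASD males, fit to 2014 IAN cumulative age-of-first-diagnosis counts"
  },
  {
    "name": "asd_female",
    "k1": 0.12532,
    "k2": 0.031716,
    "m1": 17,
    "r": 1.0,
    "time_unit": "month",
    "note": "ASD females, fit to 2014 IAN cumulative age-of-first-diagnosis counts"
  },
  {
    "name": "schizophrenia",
    "k1": 0.10757,
    "k2": 0.029959,
    "m1": 15,
    "r": 1.0,
    "time_unit": "year",
    "note": "Schizophrenia (both sexes), rates per year; converted to per-month on load"
  }
]
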