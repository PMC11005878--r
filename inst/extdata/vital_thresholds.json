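[
  {"label": "0 days to 1 week",   "lower_days": 0.0,     "upper_days": 7.0,     "tachycardia_bpm": 180, "bradycardia_bpm": 100,  "rr_threshold": 50},
  {"label": "1 week to 1 month",  "lower_days": 7.0,     "upper_days": 30.4375, "tachycardia_bpm": 180, "bradycardia_bpm": 100,  "rr_threshold": 40},
  {"label": "1 month to 1 year",  "lower_days": 30.4375, "upper_days": 730.5,   "tachycardia_bpm": 180, "bradycardia_bpm": 90,   "rr_threshold": 34},
  {"label": "2-5 years",          "lower_days": 730.5,   "upper_days": 2191.5,  "tachycardia_bpm": 140, "bradycardia_bpm": null, "rr_threshold": 22},
  {"label": "6-12 years",         "lower_days": 2191.5,  "upper_days": 4748.25, "tachycardia_bpm": 130, "bradycardia_bpm": null, "rr_threshold": 18},
  {"label": "13-18 years",        "lower_days": 4748.25, "upper_days": 6575.0,  "tachycardia_bpm": 110, "bradycardia_bpm": null, "rr_threshold": 14}
]
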