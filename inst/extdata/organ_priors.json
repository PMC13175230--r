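{
  "_note": "SYNTHETIC PLACEHOLDER literature priors for the six consensus organ systems. Values are plausible means and between-study standard deviations assembled from published IVIM meta-analyses and reviews; they are NOT a reproduction of any single published table. Replace with study-specific constants (get_preset(..., priors_file=)) for exact reproduction of externally derived numbers. Units: f dimensionless, D and Dstar in mm2/s.",
  "brain":    {"f": {"mean": 0.05, "sd": 0.03},  "D": {"mean": 0.00075, "sd": 0.00015}, "Dstar": {"mean": 0.011, "sd": 0.004}},
  "breast":   {"f": {"mean": 0.07, "sd": 0.04},  "D": {"mean": 0.0014,  "sd": 0.0003},  "Dstar": {"mean": 0.020, "sd": 0.010}},
  "kidney":   {"f": {"mean": 0.12, "sd": 0.08},  "D": {"mean": 0.0020,  "sd": 0.0002},  "Dstar": {"mean": 0.040, "sd": 0.015}},
  "liver":    {"f": {"mean": 0.25, "sd": 0.10},  "D": {"mean": 0.0011,  "sd": 0.0002},  "Dstar": {"mean": 0.060, "sd": 0.030}},
  "muscle":   {"f": {"mean": 0.08, "sd": 0.04},  "D": {"mean": 0.0015,  "sd": 0.0002},  "Dstar": {"mean": 0.025, "sd": 0.012}},
  "pancreas": {"f": {"mean": 0.12, "sd": 0.06},  "D": {"mean": 0.0013,  "sd": 0.0003},  "Dstar": {"mean": 0.025, "sd": 0.012}}
}
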