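{
  "model": "polygenic",
  "seed": 7,
  "landscape": {
    "family": "power",
    "theta": 20,
    "c_m": 0.6,
    "c_f": 0.6,
    "b_m": 1.5,
    "b_f": 1.5
  },
  "architecture": {
    "L": 10,
    "delta": 1,
    "mu": 5e-06,
    "r_adjacent": 0.5,
    "mode": "autosome"
  },
  "demography": {
    "n_per_sex": 1000,
    "generations": 5000,
    "sample_every": 100,
    "sample_size": 100
  }
}
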