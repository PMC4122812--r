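{
  "taxon": "Betula",
  "beta0": -25.413,
  "beta_day": 0.274,
  "beta_t": 0.352,
  "source": "Krakow 1991-2010 reference fit (5-day running mean of mean temperature)"
}
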