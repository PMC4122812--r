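{
  "taxon": "Corylus",
  "beta0": -4.155,
  "beta_day": 0.074,
  "beta_t": 0.215,
  "source": "Krakow 1991-2010 reference fit (5-day running mean of maximum temperature)"
}
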