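# Demo pipeline config: simulate the six preset cultivars for two years
# and produce a full evaluation report.
seed: 20160909
s_max: 30
years: [2016, 2017]
n_plants: 84
cultivars:
  - preset: jk665_like
  - preset: jk968_like
  - preset: xd20_like
  - preset: zd958_like
  - preset: jd38_like
  - preset: xy335_like
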