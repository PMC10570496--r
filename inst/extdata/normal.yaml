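# Normal (healthy) parameter set: the network settles to low-amplitude
# noise-driven fluctuations with no beta peak.
stn: {H: 20, x: 0.006, r: 300, "y": 0.1}
gpe: {H: 20, x: 0.014, r: 400, "y": 0.1}
ppn: {H: 20, x: 0.005, r: 200, "y": 0.1}
coupling:
  lambda1: 1.12
  lambda2: 19
  lambda3: 6.6
  lambda4: 10
  lambda5: 3
inputs:
  cor_mean: 27
  cor_sd: 0.1
  str_mean: 2
  str_sd: 0.1
  gpi_mean: 20
  gpi_sd: 0.1
simulation: {T: 3, dt: 0.0001, onset: 1}
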