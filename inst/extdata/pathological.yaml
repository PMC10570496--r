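# Pathological (parkinsonian) parameter set: strong GPe->STN inhibition,
# weakened GPe self-inhibition, producing ~22 Hz beta oscillations.
stn: {H: 20, x: 0.006, r: 300, "y": 0.1}
gpe: {H: 20, x: 0.014, r: 400, "y": 0.1}
ppn: {H: 20, x: 0.005, r: 200, "y": 0.1}
coupling:
  lambda1: 5     # GPe -> STN inhibition
  lambda2: 20    # STN -> GPe excitation
  lambda3: 2     # GPe -> GPe self-inhibition
  lambda4: 13    # STN -> PPN excitation
  lambda5: 1     # PPN -> STN excitation
inputs:
  cor_mean: 27
  cor_sd: 0.1
  str_mean: 2
  str_sd: 0.1
  gpi_mean: 20
  gpi_sd: 0.1
simulation: {T: 3, dt: 0.0001, onset: 1}
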