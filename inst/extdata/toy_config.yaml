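# Small end-to-end demonstration config: a down-scaled backcross design
# (6 F1, 80 BC1 eggs, 160 BC2 eggs) with fair segregation.
simulate:
  seed: 7
  n_f1: 6
  f1_males: 4
  n_bc1_eggs: 80
  n_bc1_adults: 16
  bc1_adult_males: 8
  n_bc1_breeders_m: 6
  n_bc1_breeders_f: 6
  n_bc2_eggs: 160
  n_bc2_adults: 20
  n_founders_aus: 24
  drive:
    - chromosome: all
      parent_sex: F
      stage: MI_centromere
      d: 0.5
analysis:
  p0: auto
  background_method: raw
scan:
  simulate: true
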