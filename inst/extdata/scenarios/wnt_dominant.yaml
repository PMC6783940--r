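surfaces:
  OCT4:
  - -3.5
  - 0.0
  - 0.0
  - -2.5
  - 0.0
  - 0.0
  - 1.25
  - 0.0
  - -0.75
  - 0.0
  NANOG:
  - -3.5
  - 0.0
  - 0.0
  - -2.5
  - 0.0
  - 0.0
  - 1.25
  - 0.0
  - -0.75
  - 0.0
  FGF5:
  - -3.5
  - -0.7
  - -0.7
  - -2.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.6
  - 0.0
  PAX6:
  - -3.5
  - -0.7
  - -0.7
  - -2.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.6
  - 0.0
  P75:
  - -3.5
  - -0.7
  - -0.7
  - -2.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.6
  - 0.0
  MIXL1:
  - 3.0
  - 0.0
  - 0.0
  - 2.0
  - 0.0
  - 0.0
  - -2.0
  - 0.0
  - 0.0
  - 0.0
  T:
  - 3.0
  - 0.0
  - 0.0
  - 2.0
  - 0.0
  - 0.0
  - -2.0
  - 0.0
  - 0.0
  - 0.0
  NKX2.5:
  - 2.0
  - 0.0
  - 0.0
  - -2.0
  - 0.0
  - 0.0
  - -3.0
  - 0.0
  - 0.6
  - 0.0
  MESP1:
  - 2.0
  - 0.0
  - 0.0
  - -2.0
  - 0.0
  - 0.0
  - -3.0
  - 0.0
  - 0.6
  - 0.0
  SOX17:
  - 2.5
  - 0.0
  - 0.5
  - 2.0
  - 0.0
  - 0.0
  - -2.0
  - 0.0
  - 0.0
  - 0.0
  PDX1:
  - 2.5
  - 0.0
  - 0.5
  - 2.0
  - 0.0
  - 0.0
  - -2.0
  - 0.0
  - 0.0
  - 0.0
baseline_ct: 24.0
reference_gene: GAPDH
reference_ct: 18.0
noise_sd: 0.25
replicates: 3.0
seed: 1.0
controls:
  E8:
    OCT4: 0.0
    NANOG: 0.0
    FGF5: -0.5
    PAX6: -0.5
    P75: -0.5
    MIXL1: -0.5
    T: -0.5
    NKX2.5: -3.0
    MESP1: -3.0
    SOX17: -0.5
    PDX1: -0.5
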