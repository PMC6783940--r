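factors:
- name: FGF2
  unit: ng/mL
  levels:
  - 0.0
  - 35.0
  - 100.0
- name: TGFb
  unit: ng/mL
  levels:
  - 0.0
  - 0.7
  - 2.0
- name: CHIR
  unit: uM
  levels:
  - 0.0
  - 2.0
  - 6.0
replicates:
  Sample 1: 3.0
block_size: 9.0
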