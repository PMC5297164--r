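# Example simulation configuration: a panel matching the bundled survey's
# composition (17 respondents) ranking around the catalogue order with
# moderate agreement (Mallows dispersion 2).
dispersion: 2
seed: 42
panel:
  EN: 3
  EDr: 3
  SN: 3
  SDr: 3
  SP: 3
  BM: 2
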