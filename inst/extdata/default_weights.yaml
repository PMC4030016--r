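proliferation:
  CDK4-CCND1: 0.25
  CDK2-CCNE: 0.25
  CDK2-CCNA: 0.25
  CDK1-CCNB1: 0.25
survival:
  AKT1: 0.1666667
  BCL2: 0.1666667
  MCL1: 0.1666667
  BIRC5: 0.1666667
  BIRC2: 0.1666667
  XIAP: 0.1666667
apoptosis:
  BAX: 0.25
  CASP3: 0.25
  NOXA: 0.25
  CASP8: 0.25
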