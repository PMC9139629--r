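lung:
  I0: 1.68
  alpha_org: 0.129
breast_left:
  I0: 0.78
  alpha_org: 0.08
breast_right:
  I0: 0.78
  alpha_org: 0.08
esophagus:
  I0: 0.61
  alpha_org: 0.274
thyroid:
  I0: 0.75
  alpha_org: 0.033
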