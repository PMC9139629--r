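lung:
  alpha1_total: 0.0144
  alpha1_fatal: 0.0101
  alpha2: 0.25
  alpha_beta_ratio: 3.0
breast_left:
  alpha1_total: 0.0144
  alpha1_fatal: 0.0028
  alpha2: 0.25
  alpha_beta_ratio: 3.0
breast_right:
  alpha1_total: 0.0144
  alpha1_fatal: 0.0028
  alpha2: 0.25
  alpha_beta_ratio: 3.0
esophagus:
  alpha1_total: 0.0015
  alpha1_fatal: 0.0014
  alpha2: 0.25
  alpha_beta_ratio: 3.0
thyroid:
  alpha1_total: 0.0144
  alpha1_fatal: 0.0028
  alpha2: 0.25
  alpha_beta_ratio: 3.0
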