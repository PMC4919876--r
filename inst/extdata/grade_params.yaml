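- class: healthy
  mu_b: 57.0
  alpha_b: 25.0
  beta_b: 2.28
  alpha_e: 20.0
  beta_e: 0.034
- class: cancerous
  mu_b: 65.0
  alpha_b: 12.0
  beta_b: 5.416666666667
  alpha_e: 12.0
  beta_e: 0.058333333333
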