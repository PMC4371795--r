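form: quadratic-exponential
params:
  a_rd: 1.0
  a_rf: 0.1
  s_bd: 1.0
  k_bd: 2.0
  s_bf: 1.5
  k_bf: 1.0
eta: 1.0
r_max: 1.0
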