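# Sidewinding on a nearly isotropic substrate (sand/mud analogue).
gait:
  A: 1.0
  phi: 0.25
  lam: 1.0
env:
  mu_t_ratio: 1.0
sim:
  n_periods: 10
output:
  dir: results
  prefix: sidewinding
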