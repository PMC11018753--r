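# example media definitions: one mapping per medium
# fields: n (refractive index), rho (kg/m^3), v (m/s),
#         alpha (1/m, optional), scatter_strength (optional)
pbs:
  n: 1.33
  rho: 1000
  v: 1497
  alpha: 5.0e+5
agarose_gel:
  n: 1.34
  rho: 1010
  v: 1520
  alpha: 3.0e+5
fixed_cell:
  n: 1.38
  rho: 1100
  v: 1600
  alpha: 5.0e+5
  scatter_strength: 0.9
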