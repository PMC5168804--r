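# Example run configuration. Every key is optional; omitted keys fall back
# to the package defaults (the historical constant/parameter tables for
# T. maritima at 80 degC, pH 7). Units: time h, liquid solutes mmol/L,
# biomass g/L, gas flows L/h at reactor T and P, pressure Pa.
constants:
  ph: 7
  temp_c: 80
  d_h2: 1.4e-4        # cm2/s; some tabulations print 1.4e-5, a power-of-ten
                      # slip — only 1.4e-4 reproduces KlaH2 = 114 1/h at
                      # 100 mL/min and H2 must out-diffuse O2
parameters:
  mu_max: 0.9         # 1/h
  h2_crit: 1.44       # mmol/L dissolved H2, full growth arrest
  n_inhib: 1
conditions:
  x0: 0.0316          # g/L inoculum
  glu0: 14            # mmol/L
  yeast0: 1           # g/L
  thio0: 0.12         # mmol/L
  q_n2: 6             # L/h (100 mL/min)
  t_end: 30           # h
solver:
  rtol: 1.0e-8
  atol: 1.0e-10
  dt: 0.02            # output grid (h); metrics are read off this grid
  k_ab: 1000          # 1/h acid-base relaxation (near-equilibrium)
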