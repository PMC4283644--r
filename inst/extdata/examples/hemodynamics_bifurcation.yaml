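application: hemodynamics
network:
  segments:
  - length: 5.0
    'n': 51.0
    A0: 10.0
    beta: 200.0
  - length: 5.0
    'n': 51.0
    A0: 6.0
    beta: 200.0
  - length: 5.0
    'n': 51.0
    A0: 6.0
    beta: 200.0
  junctions:
  - - 1
    - -2
    - -3
  inlet: 1
  outlets:
  - 2
  - 3
fluid:
  rho: 1.0
  K_R: 0.0
  p_ext: 0.0
  CFL: 0.8
inflow:
  type: half_sine
  Q_max: 3.0
  T_sys: 0.3
  T_cycle: 0.8
rcr:
- Rp: 0.2
  Rd: 1.5
  C: 0.5
  P_out: 0.0
- Rp: 0.2
  Rd: 1.5
  C: 0.5
  P_out: 0.0
coupling:
  tol: 1.0e-06
  max_subiter: 50
  relax: 0.7
time:
  dt: 0.01
  t_end: 1.6

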