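# 2D monodomain with radially varying sodium conductance: gNa ramps from
# 100% of its normal value at the bottom-left node to 300% at the top-right
# node; the activation wavefront travels faster where gNa is higher.
application: monodomain
mesh: {nx: 25, l: 10.0}
physics: {sigma: 0.1, chi: 140.0, Cm: 0.01}
time: {dt_pde: 0.1, dt_ode: 0.01, t_end: 20.0}
cell_model: hodgkin_huxley_1952
stimulus: {amplitude: 100.0, start: 0.0, duration: 1.0}
gna: {mode: radial, range: [1.0, 3.0]}
output: {save_every: 20}
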