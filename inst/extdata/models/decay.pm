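# First-order exponential decay: dx/dt = -k*x
independent t
const k = 0.5
init x = 2.0
ode x = -k*x
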