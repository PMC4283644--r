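# FitzHugh-Nagumo reduced excitable-membrane model (dimensionless).
# Initial state is the resting equilibrium at i_Stim = 0 (root of the
# nullcline intersection, frozen to 12 decimals).
independent t
const eps = 0.08
const beta = 0.7
const gamma = 0.8
const i_Stim = 0.0
init V = -1.199408035244
init W = -0.624260044055
ode V = V - V^3/3 - W + i_Stim
ode W = eps*(V + beta - gamma*W)
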