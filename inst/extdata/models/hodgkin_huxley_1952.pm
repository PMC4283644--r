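# Hodgkin-Huxley 1952 squid giant axon membrane model.
# Units: mV, ms, uA/cm^2, mS/cm^2, uF/cm^2 (Cm = 1 so uA/cm^2 == mV/ms).
# Initial state is the quiescent equilibrium (all four rates vanish at
# i_Stim = 0), obtained by root-finding on dV/dt with gates at steady state.
independent t
const Cm = 1.0 uF_per_cm2
const gNa = 120.0 mS_per_cm2
const gK = 36.0 mS_per_cm2
const gL = 0.3 mS_per_cm2
const E_Na = 50.0 mV
const E_K = -77.0 mV
const E_L = -54.387 mV
const i_Stim = 0.0 uA_per_cm2
init V = -64.996379331192
init m = 0.052955086813
init h = 0.595994124740
init n = 0.317732399761
alg alpha_m = 0.1*(V + 40)/(1 - exp(-(V + 40)/10))
alg beta_m = 4*exp(-(V + 65)/18)
alg alpha_h = 0.07*exp(-(V + 65)/20)
alg beta_h = 1/(1 + exp(-(V + 35)/10))
alg alpha_n = 0.01*(V + 55)/(1 - exp(-(V + 55)/10))
alg beta_n = 0.125*exp(-(V + 65)/80)
alg i_Na = gNa*m^3*h*(V - E_Na)
alg i_K = gK*n^4*(V - E_K)
alg i_L = gL*(V - E_L)
ode V = (i_Stim - i_Na - i_K - i_L)/Cm
ode m = alpha_m*(1 - m) - beta_m*m
ode h = alpha_h*(1 - h) - beta_h*h
ode n = alpha_n*(1 - n) - beta_n*n
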