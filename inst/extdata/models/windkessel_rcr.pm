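# Three-element (RCR) Windkessel: proximal resistance Rp in series with a
# parallel compliance C / distal resistance Rd, draining to venous pressure
# P_out. Q_in is the imposed inflow; P_in is the pressure seen at the inlet.
independent t
const Rp = 0.1
const Rd = 1.0
const C = 2.0
const P_out = 0.0
const Q_in = 0.0
init Pc = 0.0
ode Pc = (Q_in - (Pc - P_out)/Rd)/C
alg P_in = Pc + Rp*Q_in
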