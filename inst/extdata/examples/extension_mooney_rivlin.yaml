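# Stress-controlled uniaxial extension of an incompressible Mooney-Rivlin
# material, solved by Newton with the linked constitutive evaluation solver.
application: extension
material: {c1: 2.0, c2: 1.0}
targets: [0.0, 5.0, 10.0, 21.0, 42.0]
solver: {tol: 1.0e-10, max_iter: 50}
curve: {lambda_min: 0.5, lambda_max: 3.0, n_points: 26}
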