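# Incompressible Mooney-Rivlin hyperelastic law on the uniaxial path
# (lambda_r = lambda_theta = lambda^(-1/2); lateral traction-free, so the
# hydrostatic pressure is eliminated analytically). Pure algebraic model:
# no states. sigma_zz is the axial Cauchy stress, W the strain energy.
# E11/E22/E33 are the Green-Lagrange strain components of the same path.
independent t
const c1 = 2.0 kPa
const c2 = 1.0 kPa
const lambda = 1.0
alg I1 = lambda^2 + 2/lambda
alg I2 = 2*lambda + 1/lambda^2
alg W = c1*(I1 - 3) + c2*(I2 - 3)
alg sigma_zz = 2*(lambda^2 - 1/lambda)*(c1 + c2/lambda)
alg E11 = (lambda^2 - 1)/2
alg E22 = (1/lambda - 1)/2
alg E33 = (1/lambda - 1)/2
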