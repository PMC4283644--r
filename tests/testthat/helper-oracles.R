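# Independently hand-coded right-hand sides for every shipped model file.
# These are the oracles the compiled black boxes are checked against; they
# deliberately do not go through the model parser or code generator.

oracle_decay <- function(x, k) -k * x

oracle_hh <- function(V, m, h, n, gNa = 120, i_stim = 0,
                      gK = 36, gL = 0.3, ENa = 50, EK = -77, EL = -54.387, Cm = 1) {
  am <- 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10))
  bm <- 4 * exp(-(V + 65) / 18)
  ah <- 0.07 * exp(-(V + 65) / 20)
  bh <- 1 / (1 + exp(-(V + 35) / 10))
  an <- 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10))
  bn <- 0.125 * exp(-(V + 65) / 80)
  iNa <- gNa * m^3 * h * (V - ENa)
  iK <- gK * n^4 * (V - EK)
  iL <- gL * (V - EL)
  list(rates = c((i_stim - iNa - iK - iL) / Cm,
                 am * (1 - m) - bm * m,
                 ah * (1 - h) - bh * h,
                 an * (1 - n) - bn * n),
       i_Na = iNa, i_K = iK, i_L = iL)
}

oracle_fhn <- function(V, W, i_stim = 0, eps = 0.08, beta = 0.7, gamma = 0.8) {
  c(V - V^3 / 3 - W + i_stim, eps * (V + beta - gamma * W))
}

oracle_windkessel <- function(Pc, Q_in, Rp = 0.1, Rd = 1, C = 2, P_out = 0) {
  list(rate = (Q_in - (Pc - P_out) / Rd) / C, P_in = Pc + Rp * Q_in)
}

# Mooney-Rivlin axial stress via numerical differentiation of the energy
# (sigma_zz = lambda dW/dlambda on the incompressible uniaxial path) --
# independent of the closed form used in the package
oracle_mr_stress <- function(lambda, c1, c2, h = 1e-7) {
  W <- function(l) c1 * (l^2 + 2 / l - 3) + c2 * (2 * l + 1 / l^2 - 3)
  lambda * (W(lambda + h) - W(lambda - h)) / (2 * h)
}

# builders used across test files -----------------------------------------

decay_definition <- function(k = 0.5, x0 = 2.0) {
  parse_model(sprintf("const k = %g\ninit x = %g\node x = -k*x", k, x0), name = "decay")
}

make_decay_env <- function(k_known = TRUE, k = 0.5, x0 = 2.0) {
  env <- pm_environment()
  import_model(env, decay_definition(k, x0))
  if (k_known) flag_variable(env, 1L, "k", known = TRUE)
  env
}

make_hh_model <- function(flag_gna = TRUE, flag_ina = FALSE) {
  env <- pm_environment()
  import_model(env, read_model(shipped_model_path("hodgkin_huxley_1952")))
  flag_variable(env, 1L, "i_Stim", known = TRUE)
  if (flag_gna) flag_variable(env, 1L, "gNa", known = TRUE)
  if (flag_ina) flag_variable(env, 1L, "i_Na", wanted = TRUE)
  suppressWarnings(instantiate(env))[[1L]]
}
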