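# The point-model text format, the environment/flagging workflow, and the
# compiled black-box contract.

test_that("the parser builds validated definitions and orders algebraics", {
  d <- parse_model("const k = 0.5\node x = -k*x\ninit x = 2.0", name = "decay")
  expect_s3_class(d, "pm_definition")
  expect_named(d$odes, "x")
  expect_equal(d$constants$k, 0.5)
  expect_equal(d$initial_values$x, 2.0)
  expect_equal(d$independent, "t")

  # algebraics are topologically sorted regardless of declaration order
  d2 <- parse_model(c("const a = 1", "alg q = r + a", "alg r = a*2",
                      "init x = 0", "ode x = q"), name = "topo")
  expect_equal(names(d2$algebraics), c("r", "q"))

  # units are carried as annotations
  hh <- read_model(shipped_model_path("hodgkin_huxley_1952"))
  expect_equal(hh$units$gNa, "mS_per_cm2")
  expect_equal(length(hh$odes), 4L)
  expect_setequal(names(hh$odes), c("V", "m", "h", "n"))
  expect_true(all(c("gNa", "E_Na") %in% names(hh$constants)))
  expect_true("i_Na" %in% names(hh$algebraics))
})

test_that("parse errors name the offending symbol or construct", {
  expect_error(parse_model("init x = 2\node x = -k*x"), "undefined symbol k")
  expect_error(parse_model("const k = 1\nconst k = 2"), "duplicate definition of 'k'")
  expect_error(parse_model(c("const c = 1", "alg a = b + c", "alg b = a",
                             "init x = 0", "ode x = a")), "algebraic cycle")
  expect_error(parse_model("ode x = 1"), "no init")
  expect_error(parse_model("const k = 1\nwhatever y"), "cannot parse model statement")
  # only whitelisted functions may appear in expressions
  expect_error(parse_model("init x = 0\node x = system('ls')"), "not permitted")
})

test_that("imports return sequential indices and apply the default flags", {
  env <- pm_environment()
  expect_equal(import_model(env, decay_definition()), 1L)
  expect_equal(import_model(env, read_model(shipped_model_path("fitzhugh_nagumo"))), 2L)
  # default: states and the independent variable known+wanted, nothing else
  expect_equal(fieldpoint:::pm_get_flag(env, 1L, "x"), list(known = TRUE, wanted = TRUE))
  expect_equal(fieldpoint:::pm_get_flag(env, 1L, "t"), list(known = TRUE, wanted = TRUE))
  expect_equal(fieldpoint:::pm_get_flag(env, 1L, "k"), list(known = FALSE, wanted = FALSE))

  suppressWarnings(instantiate(env))
  expect_error(import_model(env, decay_definition()), "finished")
  expect_error(flag_variable(env, 1L, "k", known = TRUE), "finished")
})

test_that("flagging validates names and protects the independent variable", {
  env <- make_decay_env(k_known = FALSE)
  expect_error(flag_variable(env, 1L, "zz", known = TRUE), "no variable zz")
  expect_error(flag_variable(env, 5L, "k", known = TRUE), "no model with index 5")
  expect_error(flag_variable(env, 1L, "t", known = FALSE, wanted = TRUE),
               "cannot be flagged unknown")
  # a state flagged neither known nor wanted is integrated with a warning
  flag_variable(env, 1L, "x", known = FALSE, wanted = FALSE)
  expect_warning(instantiate(env), "neither known nor wanted")
})

test_that("instantiation bakes unflagged constants and fixes vector orders", {
  # k known: passed through the KNOWN vector
  m_known <- instantiate(make_decay_env(k_known = TRUE))[[1L]]
  expect_equal(m_known$known_order, "k")
  r1 <- evaluate_model(m_known, 0.0, 2.0, 0.5)
  expect_identical(r1$rates, -1.0)
  expect_length(r1$wanted, 0L)

  # k unflagged: baked into the compiled expression
  m_baked <- instantiate(make_decay_env(k_known = FALSE))[[1L]]
  expect_equal(m_baked$n_known, 0L)
  r2 <- evaluate_model(m_baked, 0.0, 2.0, numeric(0))
  expect_identical(r2$rates, -1.0)

  # baking equivalence at random points
  set.seed(42)
  for (i in 1:25) {
    x <- runif(1, -5, 5)
    expect_equal(evaluate_model(m_known, 0, x, 0.5)$rates,
                 evaluate_model(m_baked, 0, x, numeric(0))$rates,
                 tolerance = 1e-14)
  }

  # wanted intermediates appear in declaration order
  hh <- make_hh_model(flag_gna = TRUE, flag_ina = TRUE)
  expect_equal(hh$wanted_order, "i_Na")
  expect_equal(hh$known_order, c("gNa", "i_Stim"))
  expect_equal(hh$state_order, c("V", "m", "h", "n"))
  # order stability: a fresh instantiation gives identical orders
  hh2 <- make_hh_model(flag_gna = TRUE, flag_ina = TRUE)
  expect_identical(hh$known_order, hh2$known_order)
  expect_identical(hh$wanted_order, hh2$wanted_order)
})

test_that("evaluate is pure and validates its input lengths", {
  m <- make_hh_model()
  st <- m$initial_state + c(3, 0.01, -0.02, 0.01)
  a <- evaluate_model(m, 0.5, st, m$default_known)
  b <- evaluate_model(m, 0.5, st, m$default_known)
  expect_identical(a, b)
  expect_error(evaluate_model(m, 0, st[-1L], m$default_known), "expected 4 states")
  expect_error(evaluate_model(m, 0, st, numeric(0)), "expected 2 known")
})

test_that("the RCR Windkessel black box reproduces its stated ODE", {
  env <- pm_environment()
  defn <- read_model(shipped_model_path("windkessel_rcr"))
  defn <- pm_set_constant(defn, "Rd", 1)
  defn <- pm_set_constant(defn, "C", 2)
  defn <- pm_set_constant(defn, "P_out", 0)
  import_model(env, defn)
  flag_variable(env, 1L, "Q_in", known = TRUE)
  m <- instantiate(env)[[1L]]
  # dPc/dt = (Q - (Pc - P_out)/Rd)/C = (5 - 0)/2
  expect_equal(evaluate_model(m, 0, 0, 5)$rates, 2.5)
})

test_that("every shipped model matches its hand-coded oracle at random points", {
  set.seed(101)
  n_pts <- 100L

  # decay (k through the known vector)
  m <- instantiate(make_decay_env(k_known = TRUE))[[1L]]
  for (i in seq_len(n_pts)) {
    x <- runif(1, -10, 10); k <- runif(1, 0.1, 3)
    expect_equal(evaluate_model(m, 0, x, k)$rates, oracle_decay(x, k), tolerance = 1e-12)
  }

  # Hodgkin-Huxley (gNa and i_Stim known, i_Na wanted)
  hh <- make_hh_model(flag_gna = TRUE, flag_ina = TRUE)
  for (i in seq_len(n_pts)) {
    st <- c(runif(1, -90, 40), runif(3, 0.02, 0.98))
    kn <- c(runif(1, 60, 360), runif(1, -20, 80))
    got <- evaluate_model(hh, 0, st, kn)
    want <- oracle_hh(st[1], st[2], st[3], st[4], gNa = kn[1], i_stim = kn[2])
    expect_equal(got$rates, want$rates, tolerance = 1e-12)
    expect_equal(unname(got$wanted["i_Na"]), want$i_Na, tolerance = 1e-12)
  }

  # FitzHugh-Nagumo (all constants baked)
  env <- pm_environment()
  import_model(env, read_model(shipped_model_path("fitzhugh_nagumo")))
  fhn <- instantiate(env)[[1L]]
  for (i in seq_len(n_pts)) {
    st <- runif(2, -2.5, 2.5)
    expect_equal(evaluate_model(fhn, 0, st, numeric(0))$rates,
                 oracle_fhn(st[1], st[2]), tolerance = 1e-12)
  }

  # RCR Windkessel
  env <- pm_environment()
  import_model(env, read_model(shipped_model_path("windkessel_rcr")))
  for (nm in c("Q_in", "Rp", "Rd", "C", "P_out")) flag_variable(env, 1L, nm, known = TRUE)
  flag_variable(env, 1L, "P_in", wanted = TRUE)
  wk <- instantiate(env)[[1L]]
  expect_equal(wk$known_order, c("Rp", "Rd", "C", "P_out", "Q_in"))
  for (i in seq_len(n_pts)) {
    pc <- runif(1, -5, 20); q <- runif(1, -2, 8)
    rp <- runif(1, 0.05, 0.5); rd <- runif(1, 0.5, 3)
    cc <- runif(1, 0.1, 3); po <- runif(1, 0, 5)
    got <- evaluate_model(wk, 0, pc, c(rp, rd, cc, po, q))
    want <- oracle_windkessel(pc, q, rp, rd, cc, po)
    expect_equal(got$rates, want$rate, tolerance = 1e-12)
    expect_equal(unname(got$wanted["P_in"]), want$P_in, tolerance = 1e-12)
  }

  # Mooney-Rivlin (pure algebraic; stress checked against the energy
  # derivative, an independent route)
  env <- pm_environment()
  import_model(env, read_model(shipped_model_path("mooney_rivlin")))
  flag_variable(env, 1L, "lambda", known = TRUE)
  flag_variable(env, 1L, "c1", known = TRUE)
  flag_variable(env, 1L, "c2", known = TRUE)
  flag_variable(env, 1L, "sigma_zz", wanted = TRUE)
  mr <- instantiate(env)[[1L]]
  expect_equal(mr$n_states, 0L)
  for (i in seq_len(n_pts)) {
    l <- runif(1, 0.5, 3); c1 <- runif(1, 0.1, 5); c2 <- runif(1, 0, 3)
    got <- evaluate_model(mr, 0, numeric(0), c(c1, c2, l))$wanted["sigma_zz"]
    expect_equal(unname(got), oracle_mr_stress(l, c1, c2), tolerance = 1e-6)
  }
})

test_that("the HH initial state is a quiescent equilibrium", {
  m <- make_hh_model()
  r <- evaluate_model(m, 0, m$initial_state, m$default_known)
  expect_lt(max(abs(r$rates)), 1e-6)

  # subthreshold displacement relaxes back: dV/dt < 0 for V at rest + 10 mV
  st <- m$initial_state
  st[1L] <- st[1L] + 10
  expect_lt(evaluate_model(m, 0, st, m$default_known)$rates[1L], 0)
})
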