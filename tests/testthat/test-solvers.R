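# Integrator steps, the two point-model solvers, control loops, and the
# Newton solver with linked solvers.

decay_unit <- function() {
  env <- pm_environment()
  import_model(env, decay_definition(k = 1, x0 = 1))
  instantiate(env)[[1L]]
}

test_that("explicit steps reproduce closed-form decay arithmetic", {
  m05 <- instantiate(make_decay_env(k_known = FALSE))[[1L]]  # k = 0.5 baked
  expect_equal(step_euler(m05, 0, 2, numeric(0), h = 0.1), 1.9)

  m <- decay_unit()
  x <- 1
  for (i in 1:10) x <- step_euler(m, 0, x, numeric(0), 0.1)
  expect_equal(x, 0.9^10, tolerance = 1e-14)
  expect_equal(x, 0.3486784401, tolerance = 1e-10)

  x <- 1
  for (i in 1:10) x <- step_rk4(m, 0, x, numeric(0), 0.1)
  expect_equal(x, exp(-1), tolerance = 1e-6)

  expect_error(step_euler(m, 0, 1, numeric(0), h = 0), "> 0")
  # a model that blows up produces a named non-finite-rate error
  bad <- parse_model("init x = 1\node x = 1/(x - 1)")
  envb <- pm_environment(); import_model(envb, bad)
  mb <- suppressWarnings(instantiate(envb))[[1L]]
  expect_error(step_euler(mb, 0, 1, numeric(0), 0.1), "non-finite rate")
})

test_that("empirical convergence orders match the schemes", {
  m <- decay_unit()
  final <- function(stepper, h) {
    x <- 1
    for (i in seq_len(round(1 / h))) x <- stepper(m, (i - 1) * h, x, numeric(0), h)
    x
  }
  richardson <- function(stepper, h) {
    d1 <- abs(final(stepper, h) - final(stepper, h / 2))
    d2 <- abs(final(stepper, h / 2) - final(stepper, h / 4))
    log2(d1 / d2)
  }
  expect_gte(richardson(step_rk4, 0.1), 3.9)
  p_euler <- richardson(step_euler, 0.1)
  expect_gte(p_euler, 0.9); expect_lte(p_euler, 1.1)
})

test_that("integration_solve advances DOFs independently with per-DOF knowns", {
  m <- create_structured_mesh(1, 2, 1, 1)   # 6 nodes
  env <- make_decay_env()
  f <- new_field("p", m)
  add_field_variable(f, "u", list(k = list(structure = "node", default = 0.5)))
  ms <- map_set(env)
  add_map(ms, "field_to_model", get_component(f, "u", "k"), 1L, "k")
  finish_maps(ms)
  mf <- create_model_fields(ms)

  # identical inputs give identical trajectories
  integration_solve(ms, mf, 0, 1, 0.1, "euler")
  x <- mf_column(mf, "state", "x")
  expect_true(all(x == x[1L]))
  expect_equal(x[1L], 2 * 0.95^10, tolerance = 1e-14)

  # per-DOF k from the mapped field
  mf2 <- create_model_fields(ms)
  set_all_dofs(get_component(f, "u", "k"), c(rep(0.5, 3), rep(1.0, 3)))
  integration_solve(ms, mf2, 0, 1, 0.1, "euler")
  x2 <- mf_column(mf2, "state", "x")
  expect_equal(x2, c(rep(2 * 0.95^10, 3), rep(2 * 0.9^10, 3)), tolerance = 1e-14)

  # truncated last substep lands exactly on t_stop
  mf3 <- create_model_fields(ms)
  integration_solve(ms, mf3, 0, 0.25, 0.1, "euler")
  expect_equal(mf_column(mf3, "state", "x")[1L], 2 * 0.95^2 * (1 - 0.5 * 0.05),
               tolerance = 1e-14)

  expect_error(integration_solve(ms, mf, 1, 1, 0.1), "exceed")
  expect_error(integration_solve(ms, mf, 0, 1, -0.1), "> 0")
})

test_that("evaluation_solve writes intermediates without advancing states", {
  env <- pm_environment()
  import_model(env, read_model(shipped_model_path("mooney_rivlin")))
  flag_variable(env, 1L, "lambda", known = TRUE)
  flag_variable(env, 1L, "sigma_zz", wanted = TRUE)
  locs <- cbind(1:4, 0)
  f <- new_field("mat", NULL)
  add_field_variable(f, "u", list(lambda = list(structure = "data_point", locations = locs, default = 1),
                                  sigma = list(structure = "data_point", locations = locs)))
  ms <- map_set(env)
  add_map(ms, "field_to_model", get_component(f, "u", "lambda"), 1L, "lambda")
  add_map(ms, "model_to_field", get_component(f, "u", "sigma"), 1L, "sigma_zz")
  finish_maps(ms)
  mf <- create_model_fields(ms)
  lam <- c(1, 1.2, 1.5, 2)
  set_all_dofs(get_component(f, "u", "lambda"), lam)
  evaluation_solve(ms, mf, voi = 0)
  sig <- get_component(f, "u", "sigma")$values
  expect_equal(sig, 2 * (lam^2 - 1 / lam) * (2 + 1 / lam), tolerance = 1e-13)

  # idempotent on all fields
  before <- list(sig = sig, lam = get_component(f, "u", "lambda")$values)
  evaluation_solve(ms, mf, voi = 0)
  expect_identical(get_component(f, "u", "sigma")$values, before$sig)
  expect_identical(get_component(f, "u", "lambda")$values, before$lam)

  # disabled DOF keeps its intermediate row
  set_models_value(mf, 2L, 0L)
  set_all_dofs(get_component(f, "u", "lambda"), lam * 1.5)
  evaluation_solve(ms, mf, voi = 0)
  expect_equal(get_component(f, "u", "sigma")$values[2L], before$sig[2L])
})

test_that("control loops nest, tile the parent step and trace execution", {
  counter <- new.env(); counter$n <- 0L
  child <- control_loop("ode", 0, 1, 0.01,
                        solvers = list(solver("cell", "integrate",
                                              function(t0, t1) counter$n <- counter$n + 1L)))
  parent <- control_loop("time", 0, 1, 0.1, children = list(child))
  trace <- run_control_loop(parent)
  expect_equal(counter$n, 100L)           # 10 parent steps x 10 child substeps
  expect_equal(nrow(trace), 100L)
  expect_equal(unique(trace$loop), "ode")

  # solvers and sub-loops are mutually exclusive
  expect_error(control_loop("bad", 0, 1, 0.1, children = list(child),
                            solvers = list(solver("s", "custom", function(t0, t1) NULL))),
               "not both")
  # a child dt that does not divide the parent dt is rejected at construction
  expect_error(control_loop("time", 0, 1, 0.1,
                            children = list(control_loop("c", 0, 1, 0.03,
                                                         solvers = list()))),
               "does not divide")

  # two solvers in one loop alternate strictly
  tr2 <- run_control_loop(control_loop("loop", 0, 0.5, 0.1,
    solvers = list(solver("first", "custom", function(t0, t1) NULL),
                   solver("second", "custom", function(t0, t1) NULL))))
  expect_equal(tr2$solver, rep(c("first", "second"), 5))

  # trace determinism
  expect_identical(run_control_loop(parent), trace)
})

test_that("newton_solve converges, honours linked solvers and reports failures", {
  s <- newton_solve(function(x) x^2 - 4, 3, tol = 1e-10)
  expect_equal(s$x, 2, tolerance = 1e-10)
  expect_lte(s$iterations, 8L)

  # residual already below tolerance: no iterations
  s0 <- newton_solve(function(x) x - 1, 1 + 1e-12, tol = 1e-10)
  expect_equal(s0$iterations, 0L)

  # linked solvers run inside every residual evaluation
  store <- new.env(); store$calls <- 0L; store$y <- NA_real_
  linked <- function(x) { store$calls <- store$calls + 1L; store$y <- x[1L]^3 }
  s1 <- newton_solve(function(x) store$y - 8, 1.5, linked = list(linked))
  expect_equal(s1$x, 2, tolerance = 1e-9)
  expect_gt(store$calls, s1$iterations)   # called for the FD Jacobian too

  expect_error(newton_solve(function(x) 1 + 0 * x, 0), "singular Jacobian")
  expect_error(newton_solve(function(x) x^2 + 1, 0.5, max_iter = 10L),
               "did not converge")
})
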