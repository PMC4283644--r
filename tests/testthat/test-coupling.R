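# Field maps, DOF-pattern derivation and compatibility, the model-backing
# fields, and the transfer protocol.

mesh22 <- function() create_structured_mesh(2, 2, 1, 1)

# a decay model mapped to one node field for k (in) and nothing out
decay_mapset <- function(mesh = mesh22(), k_known = TRUE) {
  env <- make_decay_env(k_known = k_known)
  f <- new_field("params", mesh)
  add_field_variable(f, "u", list(k = list(structure = "node", default = 0.5)))
  ms <- map_set(env)
  add_map(ms, "field_to_model", get_component(f, "u", "k"), 1L, "k")
  list(env = env, field = f, ms = ms)
}

test_that("maps validate flag direction, component and uniqueness", {
  env <- make_decay_env(k_known = FALSE)    # k unflagged
  m <- mesh22()
  f <- new_field("params", m)
  add_field_variable(f, "u", list(k = list(structure = "node")))
  ms <- map_set(env)
  expect_error(add_map(ms, "field_to_model", get_component(f, "u", "k"), 1L, "k"),
               "flagged known")
  expect_error(add_map(ms, "model_to_field", get_component(f, "u", "k"), 1L, "k"),
               "flagged wanted")
  expect_error(add_map(ms, "field_to_model", "not a component", 1L, "k"),
               "unknown component")
  expect_error(add_map(ms, "field_to_model", get_component(f, "u", "k"), 3L, "k"),
               "no model with index")
  expect_error(add_map(ms, "field_to_model", get_component(f, "u", "k"), 1L, "qq"),
               "no variable qq")

  # an intermediate not flagged wanted cannot be exported
  env2 <- pm_environment()
  import_model(env2, read_model(shipped_model_path("hodgkin_huxley_1952")))
  f2 <- new_field("cur", m)
  add_field_variable(f2, "u", list(ina = list(structure = "node")))
  ms2 <- map_set(env2)
  expect_error(add_map(ms2, "model_to_field", get_component(f2, "u", "ina"), 1L, "i_Na"),
               "flagged wanted")

  # no fan-in: one map per (model, variable, direction)
  env3 <- make_decay_env()
  ms3 <- map_set(env3)
  add_map(ms3, "field_to_model", get_component(f, "u", "k"), 1L, "k")
  expect_error(add_map(ms3, "field_to_model", get_component(f, "u", "k"), 1L, "k"),
               "already has")
})

test_that("finishing derives the pattern and enforces location compatibility", {
  m <- mesh22()
  env <- make_decay_env()
  flag_variable(env, 1L, "x", known = TRUE, wanted = TRUE)

  # two node components from *different* fields are compatible
  f1 <- new_field("a", m); add_field_variable(f1, "u", list(k = list(structure = "node")))
  f2 <- new_field("b", m); add_field_variable(f2, "u", list(x = list(structure = "node")))
  ms <- map_set(env)
  add_map(ms, "field_to_model", get_component(f1, "u", "k"), 1L, "k")
  add_map(ms, "model_to_field", get_component(f2, "u", "x"), 1L, "x")
  pat <- finish_maps(ms)
  expect_equal(nrow(pat), 9L)
  expect_true(ms$finished)

  # node + element structures cannot share a pattern
  env2 <- make_decay_env()
  flag_variable(env2, 1L, "x", known = TRUE, wanted = TRUE)
  f3 <- new_field("c", m); add_field_variable(f3, "u", list(x = list(structure = "element")))
  ms2 <- map_set(env2)
  add_map(ms2, "field_to_model", get_component(f1, "u", "k"), 1L, "k")
  add_map(ms2, "model_to_field", get_component(f3, "u", "x"), 1L, "x")
  expect_error(finish_maps(ms2), "incompatible DOF pattern")

  # a single constant-structure map yields a pattern of length 1
  env3 <- make_decay_env()
  f4 <- new_field("d", m); add_field_variable(f4, "u", list(k = list(structure = "constant")))
  ms3 <- map_set(env3)
  add_map(ms3, "field_to_model", get_component(f4, "u", "k"), 1L, "k")
  expect_equal(nrow(finish_maps(ms3)), 1L)
})

test_that("model fields initialise from the models' defaults", {
  s <- decay_mapset()
  finish_maps(s$ms)
  mf <- create_model_fields(s$ms)
  expect_equal(get_models_field(mf), rep(1L, 9L))            # first model everywhere
  expect_equal(mf_column(mf, "state", "x"), rep(2.0, 9L))    # initial values
  expect_equal(mf_column(mf, "param", "k"), rep(0.5, 9L))    # default knowns
  expect_error(set_models_value(mf, 7L, 99L), "no model with index 99")
  expect_error(mf_column(mf, "inter", "nope"), "no inter column")
})

test_that("transfer copies by direction and skips disabled DOFs", {
  s <- decay_mapset()
  finish_maps(s$ms)
  mf <- create_model_fields(s$ms)
  comp <- get_component(s$field, "u", "k")
  set_dof(comp, 7L, 2.0)
  transfer_in(s$ms, mf)
  expect_equal(mf_column(mf, "param", "k")[7L], 2.0)
  expect_equal(mf_column(mf, "param", "k")[1L], 0.5)

  # disabled DOF: the column row is frozen across transfers and solves
  set_models_value(mf, 3L, 0L)
  set_dof(comp, 3L, 9.9)
  transfer_in(s$ms, mf)
  expect_equal(mf_column(mf, "param", "k")[3L], 0.5)
  x_before <- mf_column(mf, "state", "x")[3L]
  integration_solve(s$ms, mf, 0, 1, 0.1)
  expect_identical(mf_column(mf, "state", "x")[3L], x_before)
  expect_lt(mf_column(mf, "state", "x")[1L], x_before)   # live DOFs decayed
})

test_that("transfer_in then transfer_out without evaluation is the identity", {
  m <- mesh22()
  env <- make_decay_env()
  flag_variable(env, 1L, "x", known = TRUE, wanted = TRUE)
  f <- new_field("a", m)
  add_field_variable(f, "u", list(k = list(structure = "node", default = 0.5),
                                  x = list(structure = "node")))
  ms <- map_set(env)
  add_map(ms, "field_to_model", get_component(f, "u", "k"), 1L, "k")
  add_map(ms, "field_to_model", get_component(f, "u", "x"), 1L, "x")
  add_map(ms, "model_to_field", get_component(f, "u", "x"), 1L, "x")
  finish_maps(ms)
  mf <- create_model_fields(ms)
  xv <- runif(9); kv <- runif(9)
  set_all_dofs(get_component(f, "u", "x"), xv)
  set_all_dofs(get_component(f, "u", "k"), kv)
  transfer_in(ms, mf)
  transfer_out(ms, mf)
  expect_identical(get_component(f, "u", "x")$values, xv)
  expect_identical(get_component(f, "u", "k")$values, kv)
})

test_that("shared-storage mode gives the same store and identical results", {
  run_sim <- function(shared) {
    m <- mesh22()
    env <- make_decay_env()
    flag_variable(env, 1L, "x", known = TRUE, wanted = TRUE)
    f <- new_field("a", m)
    add_field_variable(f, "u", list(k = list(structure = "node", default = 0.5),
                                    x = list(structure = "node", default = 2.0)))
    ms <- map_set(env)
    add_map(ms, "field_to_model", get_component(f, "u", "k"), 1L, "k")
    add_map(ms, "field_to_model", get_component(f, "u", "x"), 1L, "x")
    add_map(ms, "model_to_field", get_component(f, "u", "x"), 1L, "x")
    finish_maps(ms)
    mf <- create_model_fields(ms, shared = shared)
    set_all_dofs(get_component(f, "u", "k"), seq(0.1, 0.9, length.out = 9))
    for (i in 1:5) integration_solve(ms, mf, (i - 1) * 0.5, i * 0.5, 0.05, "rk4")
    list(x = get_component(f, "u", "x")$values, mf = mf, comp = get_component(f, "u", "x"))
  }
  a <- run_sim(FALSE)
  b <- run_sim(TRUE)
  expect_equal(a$x, b$x, tolerance = 1e-14)
  # with shared storage the column *is* the component's store (no copy)
  expect_false(identical(a$mf$state_cells[["x"]], a$comp))
  expect_true(identical(b$mf$state_cells[["x"]], b$comp))
})

test_that("mixed models per pattern use union columns and per-DOF selection", {
  m <- mesh22()
  env <- pm_environment()
  import_model(env, decay_definition(k = 1, x0 = 1))           # model 1: state x
  import_model(env, parse_model("const g = 2\ninit y = 3\node y = -g*y", name = "decay2"))
  flag_variable(env, 1L, "k", known = TRUE)
  f <- new_field("a", m)
  add_field_variable(f, "u", list(k = list(structure = "node", default = 1)))
  ms <- map_set(env)
  add_map(ms, "field_to_model", get_component(f, "u", "k"), 1L, "k")
  finish_maps(ms)
  mf <- create_model_fields(ms)
  expect_setequal(mf$state_cols, c("x", "y"))
  # DOFs 4..9 switch to model 2; its state initialises, model-1 slots are NA
  set_models_value(mf, 4:9, 2L)
  expect_equal(mf_column(mf, "state", "y")[4:9], rep(3, 6))
  integration_solve(ms, mf, 0, 1, 0.01, "rk4")
  x <- mf_column(mf, "state", "x"); y <- mf_column(mf, "state", "y")
  expect_equal(x[1:3], rep(exp(-1), 3), tolerance = 1e-6)
  expect_equal(y[4:9], rep(3 * exp(-2), 6), tolerance = 1e-6)
  expect_true(all(is.na(y[1:3])))   # unused slots hold the NA sentinel
})
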