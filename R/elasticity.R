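# Reference application 3: hyperelastic constitutive laws as plug-in point
# models. The incompressible Mooney-Rivlin law on the homogeneous uniaxial
# path (lateral faces traction-free, lambda_r = lambda_theta = lambda^(-1/2))
# gives the closed-form axial Cauchy stress
#     sigma_zz = 2 (lambda^2 - 1/lambda) (c1 + c2/lambda)
# from W = c1 (I1 - 3) + c2 (I2 - 3). The constitutive evaluation runs
# through the field-map/evaluation-solver route, and stress-controlled
# extension is solved by the Newton solver with the evaluation solver linked
# into its residual — the same linked-solver pattern a 3D finite-elasticity
# code uses.

#' Closed-form uniaxial Cauchy stress of incompressible Mooney-Rivlin
#' @param lambda principal stretch (> 0; vectorised).
#' @param c1,c2 material constants (stress units).
#' @return axial Cauchy stress `2 (lambda^2 - 1/lambda)(c1 + c2/lambda)`.
#' @export
uniaxial_stress <- function(lambda, c1, c2) {
  if (any(lambda <= 0)) stop("stretch must be positive", call. = FALSE)
  2 * (lambda^2 - 1 / lambda) * (c1 + c2 / lambda)
}

#' Mooney-Rivlin strain energy on the uniaxial path
#' @inheritParams uniaxial_stress
#' @return `c1 (I1 - 3) + c2 (I2 - 3)` with `I1 = lambda^2 + 2/lambda`,
#'   `I2 = 2 lambda + 1/lambda^2`.
#' @export
uniaxial_energy <- function(lambda, c1, c2) {
  if (any(lambda <= 0)) stop("stretch must be positive", call. = FALSE)
  c1 * (lambda^2 + 2 / lambda - 3) + c2 * (2 * lambda + 1 / lambda^2 - 3)
}

#' Build the constitutive evaluation route for a stretch pattern
#'
#' Imports the constitutive model (default: the shipped Mooney-Rivlin file),
#' flags `lambda` known and `sigma_zz` (and `W`) wanted, maps a stretch
#' field component in and stress/energy components out over an n-DOF
#' data-point pattern.
#'
#' @param n number of DOFs (material points).
#' @param c1,c2 material constants, baked into the model.
#' @param defn optional `pm_definition` to use instead of the shipped
#'   Mooney-Rivlin model (a plug-in replacement must expose a known `lambda`
#'   and a wanted `sigma_zz`).
#' @return list with the field, map set and model fields
#'   (`field`, `mapset`, `model_fields`) plus component handles.
#' @export
constitutive_route <- function(n = 1L, c1 = 2, c2 = 1, defn = NULL) {
  env <- pm_environment()
  if (is.null(defn)) {
    defn <- read_model(shipped_model_path("mooney_rivlin"))
    defn <- pm_set_constant(defn, "c1", c1)
    defn <- pm_set_constant(defn, "c2", c2)
  }
  import_model(env, defn)
  flag_variable(env, 1L, "lambda", known = TRUE)
  flag_variable(env, 1L, "sigma_zz", wanted = TRUE)
  if ("W" %in% names(defn$algebraics)) flag_variable(env, 1L, "W", wanted = TRUE)

  locs <- cbind(seq_len(n), 0)
  fld <- new_field("material", mesh = NULL)
  comps <- list(lambda = list(structure = "data_point", locations = locs, default = 1),
                sigma_zz = list(structure = "data_point", locations = locs))
  if ("W" %in% names(defn$algebraics))
    comps$W <- list(structure = "data_point", locations = locs)
  add_field_variable(fld, "uniaxial", comps)
  ms <- map_set(env)
  add_map(ms, "field_to_model", get_component(fld, "uniaxial", "lambda"), 1L, "lambda")
  add_map(ms, "model_to_field", get_component(fld, "uniaxial", "sigma_zz"), 1L, "sigma_zz")
  if ("W" %in% names(defn$algebraics))
    add_map(ms, "model_to_field", get_component(fld, "uniaxial", "W"), 1L, "W")
  finish_maps(ms)
  mf <- create_model_fields(ms)
  list(field = fld, mapset = ms, model_fields = mf,
       lambda = get_component(fld, "uniaxial", "lambda"),
       sigma_zz = get_component(fld, "uniaxial", "sigma_zz"),
       W = if ("W" %in% names(defn$algebraics)) get_component(fld, "uniaxial", "W") else NULL)
}

#' Evaluate the constitutive law at per-DOF stretches (field-map route)
#'
#' Writes the stretches into the mapped field, runs the evaluation solver
#' (one evaluate per DOF; states untouched) and reads the stress field back.
#'
#' @param lambdas numeric vector of stretches.
#' @param c1,c2 material constants.
#' @param defn optional plug-in constitutive `pm_definition`.
#' @return numeric vector of axial stresses.
#' @export
constitutive_evaluate <- function(lambdas, c1 = 2, c2 = 1, defn = NULL) {
  route <- constitutive_route(length(lambdas), c1, c2, defn)
  set_all_dofs(route$lambda, lambdas)
  evaluation_solve(route$mapset, route$model_fields, voi = 0)
  route$sigma_zz$values
}

#' Solve stress-controlled uniaxial extension
#'
#' Newton iteration on the residual `sigma_model(lambda) - sigma_target`
#' where the model stress is produced by the *linked* constitutive
#' evaluation solver (writing lambda into the mapped field, evaluating,
#' reading the stress field), not by a direct function call.
#'
#' @param sigma_target applied axial Cauchy stress.
#' @param c1,c2 material constants.
#' @param tol residual tolerance.
#' @param max_iter Newton iteration cap.
#' @param lambda0 initial stretch guess.
#' @param defn optional plug-in constitutive `pm_definition`.
#' @return `list(lambda, iterations, residual_norm)`.
#' @export
solve_extension <- function(sigma_target, c1 = 2, c2 = 1, tol = 1e-10,
                            max_iter = 50L, lambda0 = 1, defn = NULL) {
  route <- constitutive_route(1L, c1, c2, defn)
  linked_eval <- function(x) {
    set_all_dofs(route$lambda, x[1L])
    evaluation_solve(route$mapset, route$model_fields, voi = 0)
  }
  residual <- function(x) route$sigma_zz$values[1L] - sigma_target
  sol <- newton_solve(residual, lambda0, tol = tol, max_iter = max_iter,
                      linked = list(linked_eval))
  list(lambda = sol$x, iterations = sol$iterations, residual_norm = sol$residual_norm)
}

#' Stress-stretch curve of the uniaxial path (field-map route)
#'
#' @param lambdas stretches to evaluate.
#' @param c1,c2 material constants.
#' @return data.frame with `lambda`, `sigma_zz`, `W`.
#' @export
extension_curve <- function(lambdas, c1 = 2, c2 = 1) {
  route <- constitutive_route(length(lambdas), c1, c2)
  set_all_dofs(route$lambda, lambdas)
  evaluation_solve(route$mapset, route$model_fields, voi = 0)
  data.frame(lambda = lambdas, sigma_zz = route$sigma_zz$values,
             W = route$W$values)
}
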