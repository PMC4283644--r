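# Reference application 1: 2D monodomain cardiac electrophysiology.
#
# The monodomain equation  chi*Cm dV/dt = div(sigma grad V) - chi*I_ion + I_stim
# is split per time step (Godunov / first-order splitting) into
#   (i)  reaction: the ionic cell model is integrated at every node over
#        [t, t + dt_pde] with substep dt_ode (integration solver over the
#        node DOF pattern; V is a model state mapped both ways, the stimulus
#        current a known input);
#   (ii) diffusion: one implicit-Euler solve of chi*Cm dV/dt = div(sigma grad V)
#        with no-flux boundaries, bilinear Lagrange FEM (consistent mass
#        matrix), reusing a sparse Cholesky factorisation across steps.
#
# The cell model is a plug-in: Hodgkin-Huxley 1952 (exposes gNa as a known
# parameter, so sodium-conductance experiments transfer) or FitzHugh-Nagumo
# for fast smooth tests.

#' Default monodomain configuration
#'
#' Units: mm, ms, mS/mm (sigma), 1/mm (chi), uF/mm^2 (Cm). The stimulus
#' amplitude is the value handed to the cell model's `i_Stim` known input
#' (HH units: uA/cm^2, equivalently mV/ms at Cm = 1).
#'
#' @param nx elements per side (square mesh).
#' @param l side length (mm).
#' @param sigma isotropic conductivity (mS/mm).
#' @param chi surface-to-volume ratio (1/mm).
#' @param Cm membrane capacitance per tissue area (uF/mm^2).
#' @param dt_pde diffusion (PDE) time step (ms); dt_ode must divide it.
#' @param dt_ode reaction (ODE) substep (ms).
#' @param t_end simulation end (ms).
#' @param cell_model "hodgkin_huxley_1952" or "fitzhugh_nagumo".
#' @param stim_amplitude,stim_start,stim_duration stimulus protocol, applied
#'   to the leftmost half of the bottom row of nodes.
#' @param gna_mode "uniform" or "radial" (HH only).
#' @param gna_multiplier uniform gNa multiplier.
#' @param gna_range radial ramp endpoints (multipliers at the bottom-left and
#'   top-right nodes).
#' @param ode_method "euler" or "rk4".
#' @param threshold activation threshold on V (mV for HH).
#' @param shared use shared-storage backing for the model fields.
#' @return a `monodomain_config` list.
#' @export
monodomain_config <- function(nx = 25L, l = 10, sigma = 0.1, chi = 140, Cm = 0.01,
                              dt_pde = 0.1, dt_ode = 0.01, t_end = 20,
                              cell_model = "hodgkin_huxley_1952",
                              stim_amplitude = 100, stim_start = 0, stim_duration = 1,
                              gna_mode = c("uniform", "radial"), gna_multiplier = 1,
                              gna_range = c(1, 3),
                              ode_method = "euler", threshold = 0, shared = FALSE) {
  ratio <- dt_pde / dt_ode
  if (abs(ratio - round(ratio)) > 1e-9)
    stop(sprintf("dt_ode=%g must divide dt_pde=%g", dt_ode, dt_pde), call. = FALSE)
  structure(list(nx = as.integer(nx), l = l, sigma = sigma, chi = chi, Cm = Cm,
                 dt_pde = dt_pde, dt_ode = dt_ode, t_end = t_end,
                 cell_model = match.arg(cell_model, c("hodgkin_huxley_1952", "fitzhugh_nagumo")),
                 stim_amplitude = stim_amplitude, stim_start = stim_start,
                 stim_duration = stim_duration,
                 gna_mode = match.arg(gna_mode), gna_multiplier = gna_multiplier,
                 gna_range = gna_range, ode_method = ode_method,
                 threshold = threshold, shared = isTRUE(shared)),
            class = "monodomain_config")
}

#' Assemble bilinear FEM mass and stiffness matrices on a structured mesh
#'
#' Consistent mass matrix and Laplacian stiffness matrix (unit coefficient)
#' with natural (no-flux) boundaries. Row sums of K vanish, which is what
#' makes the implicit diffusion step conserve the discrete integral
#' `1' M V`.
#'
#' @param mesh an `fp_mesh_2d`.
#' @return `list(M, K)` of sparse symmetric matrices.
#' @export
assemble_fem <- function(mesh) {
  hx <- mesh$lx / mesh$nx
  hy <- mesh$ly / mesh$ny
  Kx <- (hy / hx) / 6 * matrix(c(2, -2, 1, -1, -2, 2, -1, 1, 1, -1, 2, -2, -1, 1, -2, 2), 4, 4)
  Ky <- (hx / hy) / 6 * matrix(c(2, 1, -2, -1, 1, 2, -1, -2, -2, -1, 2, 1, -1, -2, 1, 2), 4, 4)
  Ke <- Kx + Ky
  Me <- (hx * hy / 36) * matrix(c(4, 2, 2, 1, 2, 4, 1, 2, 2, 1, 4, 2, 1, 2, 2, 4), 4, 4)
  ne <- mesh$n_elements
  ii <- integer(16L * ne); jj <- integer(16L * ne)
  kv <- numeric(16L * ne); mv <- numeric(16L * ne)
  idx <- 0L
  for (e in seq_len(ne)) {
    en <- mesh$elements[e, ]
    for (a in 1:4) for (b in 1:4) {
      idx <- idx + 1L
      ii[idx] <- en[a]; jj[idx] <- en[b]
      kv[idx] <- Ke[a, b]; mv[idx] <- Me[a, b]
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = kv, dims = c(mesh$n_nodes, mesh$n_nodes))
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = mv, dims = c(mesh$n_nodes, mesh$n_nodes))
  list(M = Matrix::forceSymmetric(M), K = Matrix::forceSymmetric(K))
}

#' Radial parameter ramp over a square mesh
#'
#' Node value = `base * (f_min + (f_max - f_min) * d/d_max)` where d is the
#' Euclidean distance from the bottom-left node and d_max the distance to
#' the top-right node: 100% of base at the bottom-left corner up to
#' `f_max * base` at the top-right corner for the defaults.
#'
#' @param mesh an `fp_mesh_2d`.
#' @param base base parameter value.
#' @param f_min,f_max multipliers at the bottom-left / top-right nodes.
#' @return numeric vector over the nodes.
#' @export
radial_parameter_field <- function(mesh, base, f_min = 1, f_max = 3) {
  d <- sqrt(mesh$nodes[, 1L]^2 + mesh$nodes[, 2L]^2)
  dmax <- sqrt(mesh$lx^2 + mesh$ly^2)
  base * (f_min + (f_max - f_min) * d / dmax)
}

#' Stimulus node set: leftmost half of the bottom row
#' @param mesh an `fp_mesh_2d`.
#' @return integer node ids.
#' @export
stimulus_nodes <- function(mesh) {
  seq_len((mesh$nx + 1L) %/% 2L)
}

#' Per-node stimulus current at time t
#' @param config a `monodomain_config`.
#' @param mesh the mesh.
#' @param t time (ms).
#' @return numeric vector over nodes: amplitude on the stimulus node set
#'   while `t` is in `[stim_start, stim_start + stim_duration)`, else 0.
#' @export
apply_stimulus <- function(config, mesh, t) {
  out <- numeric(mesh$n_nodes)
  if (t >= config$stim_start && t < config$stim_start + config$stim_duration)
    out[stimulus_nodes(mesh)] <- config$stim_amplitude
  out
}

#' Run a monodomain simulation
#'
#' Builds the point-model environment, field maps and model-backing fields,
#' then executes the nested control loop: per PDE step, a reaction
#' integration solve over all node DOFs followed by one implicit-Euler
#' diffusion solve. Records activation times (first upward crossing of the
#' threshold, linearly interpolated between PDE steps) and the per-step
#' conservation error of the diffusion operator.
#'
#' @param config a `monodomain_config`.
#' @param save_every save the V field every this many PDE steps (0 = never).
#' @return an object of class `fp_monodomain_result` with `activation` (ms,
#'   NA where unactivated), `V_final`, `conservation_rel` (max per-step
#'   relative change of the mass-weighted integral of V during diffusion),
#'   `trace`, `mesh`, `config` and optionally `V_history`.
#' @export
run_monodomain <- function(config, save_every = 0L) {
  stopifnot(inherits(config, "monodomain_config"))
  mesh <- create_structured_mesh(config$nx, config$nx, config$l, config$l)
  hh <- config$cell_model == "hodgkin_huxley_1952"

  env <- pm_environment()
  defn <- read_model(shipped_model_path(config$cell_model))
  import_model(env, defn)
  flag_variable(env, 1L, "i_Stim", known = TRUE)
  if (hh) flag_variable(env, 1L, "gNa", known = TRUE)

  fld <- new_field("tissue", mesh)
  add_field_variable(fld, "vm", list(V = list(structure = "node")))
  add_field_variable(fld, "stim", list(i_Stim = list(structure = "node")))
  if (hh) add_field_variable(fld, "conductance", list(gNa = list(structure = "node")))
  v_comp <- get_component(fld, "vm", "V")
  s_comp <- get_component(fld, "stim", "i_Stim")

  ms <- map_set(env)
  add_map(ms, "field_to_model", v_comp, 1L, "V")
  add_map(ms, "model_to_field", v_comp, 1L, "V")
  add_map(ms, "field_to_model", s_comp, 1L, "i_Stim")
  if (hh) {
    g_comp <- get_component(fld, "conductance", "gNa")
    gna_base <- defn$constants[["gNa"]]
    gvals <- switch(config$gna_mode,
      uniform = rep(gna_base * config$gna_multiplier, mesh$n_nodes),
      radial = radial_parameter_field(mesh, gna_base, config$gna_range[1L], config$gna_range[2L]))
    set_all_dofs(g_comp, gvals)
    add_map(ms, "field_to_model", g_comp, 1L, "gNa")
  }
  finish_maps(ms)
  mf <- create_model_fields(ms, shared = config$shared)

  compiled <- env$compiled[[1L]]
  v0 <- compiled$initial_state[match("V", compiled$state_order)]
  set_all_dofs(v_comp, v0)

  fem <- assemble_fem(mesh)
  cc <- config$chi * config$Cm
  A <- cc * fem$M + config$dt_pde * config$sigma * fem$K
  chol_A <- Matrix::Cholesky(A, LDL = FALSE)
  M <- fem$M

  n <- mesh$n_nodes
  activation <- rep(NA_real_, n)
  prev_V <- rep(v0, n)
  prev_t <- 0
  cons_max <- 0
  n_steps <- round(config$t_end / config$dt_pde)
  V_history <- if (save_every > 0L) list() else NULL

  step_i <- 0L
  reaction <- solver("reaction_ode", "integrate", function(t0, t1) {
    set_all_dofs(s_comp, apply_stimulus(config, mesh, t0))
    integration_solve(ms, mf, t0, t1, config$dt_ode, config$ode_method)
  })
  diffusion <- solver("diffusion_pde", "parabolic", function(t0, t1) {
    V <- v_comp$values
    if (config$sigma != 0) {
      rhs <- cc * (M %*% V)
      Vn <- as.numeric(Matrix::solve(chol_A, rhs))
      before <- sum(M %*% V); after <- sum(M %*% Vn)
      cons_max <<- max(cons_max, abs(after - before) / max(1e-30, abs(before)))
      set_all_dofs(v_comp, Vn)
      V <- Vn
    }
    # activation detection at the end of the full split step
    newly <- which(is.na(activation) & prev_V < config$threshold & V >= config$threshold)
    if (length(newly)) {
      frac <- (config$threshold - prev_V[newly]) / (V[newly] - prev_V[newly])
      activation[newly] <<- prev_t + frac * (t1 - prev_t)
    }
    prev_V <<- V
    prev_t <<- t1
    step_i <<- step_i + 1L
    if (save_every > 0L && step_i %% save_every == 0L)
      V_history[[length(V_history) + 1L]] <<- V
  })
  loop <- control_loop("time", 0, config$t_end, config$dt_pde,
                       solvers = list(reaction, diffusion))
  trace <- run_control_loop(loop)

  structure(list(activation = activation, V_final = v_comp$values,
                 conservation_rel = cons_max, trace = trace,
                 mesh = mesh, config = config, V_history = V_history,
                 mapset = ms, model_fields = mf),
            class = "fp_monodomain_result")
}

#' @exportS3Method base::print
print.fp_monodomain_result <- function(x, ...) {
  act <- sum(!is.na(x$activation))
  cat(sprintf("<fp_monodomain_result>: %s on %dx%d elements, t_end=%g ms; %d/%d nodes activated; diffusion conservation (max rel per step) %.2e\n",
              x$config$cell_model, x$config$nx, x$config$nx, x$config$t_end,
              act, length(x$activation), x$conservation_rel))
  invisible(x)
}

#' Conduction velocity between two probe nodes
#'
#' CV = distance(a, b) / |t_b - t_a| from the activation map.
#'
#' @param result an `fp_monodomain_result` (or a numeric activation vector,
#'   in which case `mesh` must be given).
#' @param probe_a,probe_b node ids.
#' @param mesh the mesh (taken from `result` when omitted).
#' @return conduction velocity (mm/ms).
#' @export
conduction_velocity <- function(result, probe_a, probe_b, mesh = NULL) {
  if (inherits(result, "fp_monodomain_result")) {
    activation <- result$activation
    mesh <- result$mesh
  } else activation <- result
  ta <- activation[probe_a]; tb <- activation[probe_b]
  if (is.na(ta) || is.na(tb)) stop("probe not activated", call. = FALSE)
  if (tb == ta) stop("identical activation times at the probes", call. = FALSE)
  d <- sqrt(sum((mesh$nodes[probe_a, ] - mesh$nodes[probe_b, ])^2))
  d / abs(tb - ta)
}

#' Default CV probes: two bottom-row nodes beyond the stimulated edge
#' @param mesh an `fp_mesh_2d`.
#' @return integer vector of two node ids.
#' @export
cv_probes <- function(mesh) {
  nn <- mesh$nx + 1L
  half <- nn %/% 2L
  # past the stimulated half, with margin from both the stimulus edge and
  # the right boundary
  a <- half + max(2L, nn %/% 8L)
  b <- nn - max(2L, nn %/% 12L)
  c(a, b)
}
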