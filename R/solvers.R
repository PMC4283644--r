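# Solvers and control loops. Two point-model solvers operate on the
# model-backing fields of a map set: the integration solver advances every
# pattern DOF's model over a time window with explicit substeps, and the
# evaluation solver performs a single evaluate per DOF (rates and wanted
# intermediates recomputed, states untouched). Both follow the transfer
# protocol: transfer_in, solve, transfer_out. Control loops nest; solvers
# live only in leaf loops. A Newton solver with linked solvers completes the
# set (linked solvers execute inside the residual evaluation).

## ---- single-instance integrator steps -----------------------------------

#' One explicit Euler step of a compiled point model
#'
#' @param model a `pm_compiled`.
#' @param voi current value of the independent variable.
#' @param state state vector.
#' @param known known-parameter vector.
#' @param h step size (> 0).
#' @return the advanced state vector.
#' @export
step_euler <- function(model, voi, state, known = model$default_known, h) {
  if (h <= 0) stop("step size must be > 0", call. = FALSE)
  r <- evaluate_model(model, voi, state, known)$rates
  fp_check_rates(r, model, 1L)
  state + h * r
}

#' One classical Runge-Kutta (RK4) step of a compiled point model
#'
#' @inheritParams step_euler
#' @return the advanced state vector.
#' @export
step_rk4 <- function(model, voi, state, known = model$default_known, h) {
  if (h <= 0) stop("step size must be > 0", call. = FALSE)
  k1 <- evaluate_model(model, voi, state, known)$rates
  k2 <- evaluate_model(model, voi + h / 2, state + h / 2 * k1, known)$rates
  k3 <- evaluate_model(model, voi + h / 2, state + h / 2 * k2, known)$rates
  k4 <- evaluate_model(model, voi + h, state + h * k3, known)$rates
  fp_check_rates(k4, model, 1L)
  state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

fp_check_rates <- function(r, model, dof) {
  bad <- which(!is.finite(r))
  if (length(bad))
    stop(sprintf("non-finite rate in model '%s' at DOF %d (state slot %d)",
                 model$name, dof, ((bad[1L] - 1L) %% max(1L, model$n_states)) + 1L),
         call. = FALSE)
  invisible(NULL)
}

# batch steps over a DOF group: states n x n_states, known n x n_known
fp_batch_euler <- function(model, voi, states, known, h) {
  r <- pm_eval_batch(model, voi, states, known)$rates
  states + h * r
}

fp_batch_rk4 <- function(model, voi, states, known, h) {
  k1 <- pm_eval_batch(model, voi, states, known)$rates
  k2 <- pm_eval_batch(model, voi + h / 2, states + h / 2 * k1, known)$rates
  k3 <- pm_eval_batch(model, voi + h / 2, states + h / 2 * k2, known)$rates
  k4 <- pm_eval_batch(model, voi + h, states + h * k3, known)$rates
  states + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

## ---- point-model solvers ------------------------------------------------

# gather / scatter between cells and per-model matrices
fp_gather <- function(cells, cols, rows) {
  out <- matrix(0, nrow = length(rows), ncol = length(cols))
  for (j in seq_along(cols)) out[, j] <- fp_cell_read(cells[[cols[j]]])[rows]
  out
}
fp_scatter <- function(cells, cols, rows, mat) {
  for (j in seq_along(cols)) {
    cell <- cells[[cols[j]]]
    cell$values[rows] <- mat[, j]
  }
  invisible(NULL)
}

#' Integration solve: advance every pattern DOF's model over a time window
#'
#' Performs transfer_in, then independently integrates the model at each
#' pattern DOF from `t_start` to `t_stop` with substep `dt` (the last
#' substep is truncated to land exactly on `t_stop`), recomputes the wanted
#' intermediates at `t_stop`, and performs transfer_out. DOFs with models
#' value 0 are skipped.
#'
#' @param mapset a finished `fp_map_set`.
#' @param mf the `fp_model_fields`.
#' @param t_start,t_stop time window (`t_stop > t_start`).
#' @param dt substep (> 0).
#' @param method "euler" or "rk4".
#' @return `mf`, invisibly.
#' @export
integration_solve <- function(mapset, mf, t_start, t_stop, dt, method = c("euler", "rk4")) {
  stopifnot(inherits(mapset, "fp_map_set"), inherits(mf, "fp_model_fields"))
  method <- match.arg(method)
  if (t_stop <= t_start) stop("t_stop must exceed t_start", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  transfer_in(mapset, mf)
  stepper <- if (method == "euler") fp_batch_euler else fp_batch_rk4
  for (mi in sort(unique(mf$models))) {
    if (mi == 0L) next
    rows <- which(mf$models == mi)
    model <- mf$env$compiled[[mi]]
    states <- fp_gather(mf$state_cells, model$state_order, rows)
    known <- fp_gather(mf$param_cells, model$known_order, rows)
    t <- t_start
    while (t < t_stop - 1e-12 * max(1, abs(t_stop))) {
      h <- min(dt, t_stop - t)
      states <- stepper(model, t, states, known, h)
      if (anyNA(states) || any(!is.finite(states))) {
        bad <- which(!is.finite(states), arr.ind = TRUE)
        stop(sprintf("non-finite state in model '%s' at DOF %d", model$name,
                     rows[bad[1L, 1L]]), call. = FALSE)
      }
      t <- t + h
    }
    res <- pm_eval_batch(model, t_stop, states, known)
    fp_scatter(mf$state_cells, model$state_order, rows, states)
    if (model$n_wanted > 0L)
      fp_scatter(mf$inter_cells, model$wanted_order, rows, res$wanted)
  }
  transfer_out(mapset, mf)
  invisible(mf)
}

#' Evaluation solve: a single model evaluation at every pattern DOF
#'
#' Performs transfer_in, one evaluate per DOF (wanted intermediates written;
#' states NOT advanced), then transfer_out. Idempotent when repeated. DOFs
#' with models value 0 are skipped.
#'
#' @param mapset a finished `fp_map_set`.
#' @param mf the `fp_model_fields`.
#' @param voi value of the independent variable passed to the models.
#' @return `mf`, invisibly; the last rate matrix per model is stored in
#'   `mf$last_rates`.
#' @export
evaluation_solve <- function(mapset, mf, voi = 0) {
  stopifnot(inherits(mapset, "fp_map_set"), inherits(mf, "fp_model_fields"))
  transfer_in(mapset, mf)
  mf$last_rates <- list()
  for (mi in sort(unique(mf$models))) {
    if (mi == 0L) next
    rows <- which(mf$models == mi)
    model <- mf$env$compiled[[mi]]
    states <- fp_gather(mf$state_cells, model$state_order, rows)
    known <- fp_gather(mf$param_cells, model$known_order, rows)
    res <- pm_eval_batch(model, voi, states, known)
    if (model$n_wanted > 0L)
      fp_scatter(mf$inter_cells, model$wanted_order, rows, res$wanted)
    mf$last_rates[[as.character(mi)]] <- res$rates
  }
  transfer_out(mapset, mf)
  invisible(mf)
}

## ---- control loops ------------------------------------------------------

#' Create a solver object for use inside a control loop
#'
#' @param label solver label (appears in the execution trace).
#' @param type one of "evaluate", "integrate", "parabolic", "newton",
#'   "coupled_step", "custom".
#' @param execute function `(t0, t1)` performing the solver's work.
#' @return an object of class `fp_solver`.
#' @export
solver <- function(label, type = "custom", execute) {
  stopifnot(is.function(execute))
  structure(list(label = label, type = type, execute = execute), class = "fp_solver")
}

#' Create a (possibly nested) control loop
#'
#' A time loop runs over `[t0, t1]` in steps of `dt`; at each step it
#' executes its child loops (each child's window is the parent step, and the
#' child's `dt` must divide the parent's) or, for leaf loops, its solvers in
#' order. Solvers are only permitted in loops without children.
#'
#' @param label loop label.
#' @param t0,t1 time window.
#' @param dt time step (> 0, dividing the window).
#' @param children list of child `fp_control_loop`s (their `dt` must divide
#'   this loop's `dt`).
#' @param solvers list of `fp_solver`s (leaf loops only).
#' @return an object of class `fp_control_loop`.
#' @export
control_loop <- function(label, t0, t1, dt, children = list(), solvers = list()) {
  if (length(children) && length(solvers))
    stop("a control loop may contain solvers or sub-loops, not both", call. = FALSE)
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  for (ch in children) {
    stopifnot(inherits(ch, "fp_control_loop"))
    ratio <- dt / ch$dt
    if (abs(ratio - round(ratio)) > 1e-9)
      stop(sprintf("child loop '%s' dt=%g does not divide parent '%s' dt=%g",
                   ch$label, ch$dt, label, dt), call. = FALSE)
  }
  for (s in solvers) stopifnot(inherits(s, "fp_solver"))
  structure(list(label = label, t0 = t0, t1 = t1, dt = dt,
                 children = children, solvers = solvers),
            class = "fp_control_loop")
}

#' Execute a control-loop tree
#'
#' Depth-first execution: each time step of a loop runs its children (whose
#' windows tile the parent step) or its solvers in order. Returns the
#' execution trace.
#'
#' @param root an `fp_control_loop`.
#' @return data.frame trace with columns `loop`, `t`, `solver`, in execution
#'   order.
#' @export
run_control_loop <- function(root) {
  stopifnot(inherits(root, "fp_control_loop"))
  trace <- list()
  run1 <- function(loop, t0, t1) {
    nstep <- max(1L, round((t1 - t0) / loop$dt))
    for (k in seq_len(nstep)) {
      ta <- t0 + (k - 1L) * loop$dt
      tb <- t0 + k * loop$dt
      if (length(loop$children)) {
        for (ch in loop$children) run1(ch, ta, tb)
      } else {
        for (s in loop$solvers) {
          trace[[length(trace) + 1L]] <<- data.frame(loop = loop$label, t = ta, solver = s$label)
          s$execute(ta, tb)
        }
      }
    }
  }
  run1(root, root$t0, root$t1)
  if (!length(trace)) return(data.frame(loop = character(0), t = numeric(0), solver = character(0)))
  do.call(rbind, trace)
}

## ---- Newton solver ------------------------------------------------------

#' Newton solver with finite-difference Jacobian and linked solvers
#'
#' Solves `residual(x) = 0`. Before every residual evaluation, each linked
#' solver is executed with the current iterate (this is how, e.g., a
#' constitutive evaluation solver updates the stress fields the residual
#' reads). The Jacobian is computed by central finite differences with
#' relative perturbation 1e-7. Convergence is declared when the residual
#' infinity norm drops below `tol`.
#'
#' @param residual function `x -> numeric` (same length as `x`).
#' @param x0 initial iterate.
#' @param tol residual infinity-norm tolerance.
#' @param max_iter iteration cap.
#' @param linked list of functions `x -> ()` executed before each residual
#'   evaluation.
#' @return `list(x, iterations, residual_norm)`.
#' @export
newton_solve <- function(residual, x0, tol = 1e-10, max_iter = 50L, linked = list()) {
  r_eval <- function(x) {
    for (ls in linked) ls(x)
    as.numeric(residual(x))
  }
  x <- as.numeric(x0)
  n <- length(x)
  r <- r_eval(x)
  if (length(r) != n) stop("residual length must match x", call. = FALSE)
  it <- 0L
  while (max(abs(r)) >= tol) {
    if (it >= max_iter)
      stop(sprintf("Newton did not converge in %d iterations (residual %.3e at x = %s)",
                   max_iter, max(abs(r)), paste(signif(x, 6), collapse = ", ")), call. = FALSE)
    J <- matrix(0, n, n)
    for (j in seq_len(n)) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- x; xp[j] <- x[j] + h
      xm <- x; xm[j] <- x[j] - h
      J[, j] <- (r_eval(xp) - r_eval(xm)) / (2 * h)
    }
    dx <- tryCatch(solve(J, -r),
                   error = function(e) stop("singular Jacobian in Newton solve", call. = FALSE))
    x <- x + dx
    r <- r_eval(x)
    if (any(!is.finite(r))) stop("non-finite residual in Newton solve", call. = FALSE)
    it <- it + 1L
  }
  list(x = x, iterations = it, residual_norm = max(abs(r)))
}
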