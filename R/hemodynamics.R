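# Reference application 2: 1D network blood flow coupled to 0D RCR
# Windkessel outlet models.
#
# Governing system (per segment, conservation form):
#   dA/dt + dQ/dx = 0
#   dQ/dt + d/dx(Q^2/A + B(A)) = -K_R * Q/A,   B(A) = beta/(3 rho A0) A^(3/2)
# with the elastic tube law p = p_ext + beta (sqrt(A) - sqrt(A0)) / A0 and a
# flat velocity profile. Wave speed c = sqrt(beta/(2 rho A0)) A^(1/4);
# Riemann invariants W+- = u +- 4 (c - c0).
#
# Interior points advance by two-step (Richtmyer) Lax-Wendroff; boundary and
# junction points by characteristic matching. Terminal outlets carry RCR
# Windkessel point models (the shipped windkessel_rcr model run through the
# map/transfer machinery at a one-DOF-per-outlet pattern); each time step the
# 1D and 0D sides are fixed-point iterated until the interface pressures
# converge below a user tolerance.

#' Wave speed of the compliant 1D vessel
#' @param A current cross-sectional area.
#' @param A0 reference area.
#' @param beta wall stiffness coefficient.
#' @param rho blood density.
#' @return c = sqrt(beta/(2 rho A0)) * A^(1/4).
#' @export
wave_speed <- function(A, A0, beta, rho) {
  if (any(A <= 0) || A0 <= 0 || beta <= 0 || rho <= 0)
    stop("wave_speed: all inputs must be positive", call. = FALSE)
  sqrt(beta / (2 * rho * A0)) * A^0.25
}

#' Riemann invariants of the 1D flow system
#' @inheritParams wave_speed
#' @param Q volumetric flow.
#' @return `list(Wf, Wb)`: forward and backward invariants
#'   u +- 4 (c(A) - c(A0)).
#' @export
riemann_invariants <- function(A, Q, A0, beta, rho) {
  c_ <- wave_speed(A, A0, beta, rho)
  c0 <- wave_speed(A0, A0, beta, rho)
  u <- Q / A
  list(Wf = u + 4 * (c_ - c0), Wb = u - 4 * (c_ - c0))
}

#' Recover (A, Q) from the Riemann invariants
#' @param Wf,Wb forward/backward invariants.
#' @inheritParams wave_speed
#' @return `list(A, Q)`.
#' @export
invert_invariants <- function(Wf, Wb, A0, beta, rho) {
  c0 <- wave_speed(A0, A0, beta, rho)
  c_ <- c0 + (Wf - Wb) / 8
  if (any(c_ <= 0))
    stop("invert_invariants: Wf - Wb <= -8 c0 implies nonpositive area", call. = FALSE)
  k <- sqrt(beta / (2 * rho * A0))
  A <- (c_ / k)^4
  u <- (Wf + Wb) / 2
  list(A = A, Q = u * A)
}

#' Transmural pressure from area (elastic tube law)
#' @inheritParams wave_speed
#' @param p_ext external pressure.
#' @return p = p_ext + beta (sqrt(A) - sqrt(A0)) / A0.
#' @export
tube_pressure <- function(A, A0, beta, p_ext = 0) {
  p_ext + beta * (sqrt(A) - sqrt(A0)) / A0
}

#' Area from pressure (inverse tube law)
#' @param p pressure.
#' @inheritParams tube_pressure
#' @return area A.
#' @export
pressure_to_area <- function(p, A0, beta, p_ext = 0) {
  s <- sqrt(A0) + A0 * (p - p_ext) / beta
  if (any(s <= 0)) stop("pressure below collapse limit of the tube law", call. = FALSE)
  s^2
}

## ---- problem container --------------------------------------------------

#' Build a 1D-0D hemodynamics problem
#'
#' Bundles the network, fluid parameters, boundary conditions and (for
#' Windkessel outlets) the point-model environment, field maps and model
#' fields for the RCR models: one model instance per outlet, on a
#' one-DOF-per-outlet data-point pattern; the boundary flow field feeds the
#' model's `Q_in` (field to model) and the wanted `P_in` returns to the
#' boundary pressure field (model to field).
#'
#' @param network an `fp_network_1d`.
#' @param rho blood density.
#' @param K_R friction coefficient (Poiseuille: 22 pi nu).
#' @param p_ext external pressure.
#' @param CFL CFL number for the step-size check.
#' @param inflow function `t -> Q` imposed at the inlet (via the backward
#'   invariant), or NULL for a closed network.
#' @param rcr data.frame with one row per outlet: `Rp`, `Rd`, `C`, `P_out`.
#'   NULL makes every boundary closed (reflective).
#' @param tol interface-pressure convergence tolerance of the per-step 1D-0D
#'   fixed-point iteration.
#' @param max_subiter subiteration cap per step.
#' @param relax under-relaxation factor for the interface pressure update.
#' @param wk_substep Windkessel ODE substep; default `min(dt/4, Rd C/2)` at
#'   solve time.
#' @return an object of class `fp_hemo_problem` (mutable).
#' @export
hemo_problem <- function(network, rho = 1, K_R = 0, p_ext = 0, CFL = 0.8,
                         inflow = NULL, rcr = NULL, tol = 1e-6,
                         max_subiter = 50L, relax = 1, wk_substep = NULL) {
  stopifnot(inherits(network, "fp_network_1d"))
  pr <- new.env(parent = emptyenv())
  pr$network <- network
  pr$rho <- rho; pr$K_R <- K_R; pr$p_ext <- p_ext; pr$CFL <- CFL
  pr$inflow <- inflow
  pr$tol <- tol; pr$max_subiter <- as.integer(max_subiter); pr$relax <- relax
  pr$wk_substep <- wk_substep
  pr$t <- 0
  # rest state
  pr$A <- lapply(seq_len(network$n_segments), function(s)
    rep(network$segments$A0[s], network$segments$n[s]))
  pr$Q <- lapply(seq_len(network$n_segments), function(s)
    rep(0, network$segments$n[s]))
  pr$subiters <- integer(0)

  if (!is.null(rcr)) {
    rcr <- as.data.frame(rcr)
    stopifnot(all(c("Rp", "Rd", "C", "P_out") %in% names(rcr)),
              nrow(rcr) == length(network$outlets))
    if (any(rcr$Rp <= 0 | rcr$Rd <= 0 | rcr$C <= 0))
      stop("Rp, Rd, C must be positive", call. = FALSE)
    pr$rcr <- rcr
    n_out <- nrow(rcr)
    env <- pm_environment()
    import_model(env, read_model(shipped_model_path("windkessel_rcr")))
    for (nm in c("Q_in", "Rp", "Rd", "C", "P_out")) flag_variable(env, 1L, nm, known = TRUE)
    flag_variable(env, 1L, "P_in", wanted = TRUE)
    # one-DOF-per-outlet pattern: outlets placed at distinct dummy locations
    locs <- cbind(seq_len(n_out), 0)
    fld <- new_field("outlets", mesh = NULL)
    add_field_variable(fld, "bc", list(
      Q_in = list(structure = "data_point", locations = locs),
      P_in = list(structure = "data_point", locations = locs),
      Rp = list(structure = "data_point", locations = locs),
      Rd = list(structure = "data_point", locations = locs),
      C = list(structure = "data_point", locations = locs),
      P_out = list(structure = "data_point", locations = locs)))
    ms <- map_set(env)
    for (nm in c("Q_in", "Rp", "Rd", "C", "P_out"))
      add_map(ms, "field_to_model", get_component(fld, "bc", nm), 1L, nm)
    add_map(ms, "model_to_field", get_component(fld, "bc", "P_in"), 1L, "P_in")
    finish_maps(ms)
    mf <- create_model_fields(ms)
    for (nm in c("Rp", "Rd", "C", "P_out"))
      set_all_dofs(get_component(fld, "bc", nm), rcr[[nm]])
    pr$wk_field <- fld; pr$wk_ms <- ms; pr$wk_mf <- mf
    # interface pressures start consistent with the initial capacitor state
    pc0 <- mf_column(mf, "state", "Pc")
    pr$P_interface <- pc0   # Q = 0 initially, so P_in = Pc
  } else {
    pr$rcr <- NULL
  }
  class(pr) <- "fp_hemo_problem"
  pr
}

#' @exportS3Method base::print
print.fp_hemo_problem <- function(x, ...) {
  cat(sprintf("<fp_hemo_problem>: %d segment(s), t = %.4g%s\n",
              x$network$n_segments, x$t,
              if (!is.null(x$rcr)) sprintf(", %d RCR outlet(s)", nrow(x$rcr)) else ""))
  invisible(x)
}

#' Largest stable time step (CFL condition)
#' @param prob an `fp_hemo_problem`.
#' @return `CFL * min(dx / (|u| + c))` over all grid points.
#' @export
cfl_dt <- function(prob) {
  net <- prob$network
  dtm <- Inf
  for (s in seq_len(net$n_segments)) {
    A <- prob$A[[s]]; Q <- prob$Q[[s]]
    c_ <- wave_speed(A, net$segments$A0[s], net$segments$beta[s], prob$rho)
    smax <- max(abs(Q / A) + c_)
    dtm <- min(dtm, net$segments$dx[s] / smax)
  }
  prob$CFL * dtm
}

# flux of the conservation form
fp_hemo_flux <- function(A, Q, A0, beta, rho) {
  list(FA = Q, FQ = Q^2 / A + beta / (3 * rho * A0) * A^1.5)
}

# Richtmyer two-step Lax-Wendroff update of one segment's interior points.
# Closed (reflective) ends update the boundary node as a conservative half
# cell with zero wall mass flux and u = 0, so that the trapezoid-weighted
# total volume telescopes exactly (conserved to round-off).
fp_richtmyer <- function(A, Q, dx, dt, A0, beta, rho, K_R,
                         closed_left = FALSE, closed_right = FALSE) {
  n <- length(A)
  f <- fp_hemo_flux(A, Q, A0, beta, rho)
  sQ <- -K_R * Q / A
  i <- seq_len(n - 1L)
  Ah <- 0.5 * (A[i] + A[i + 1L]) - dt / (2 * dx) * (f$FA[i + 1L] - f$FA[i])
  Qh <- 0.5 * (Q[i] + Q[i + 1L]) - dt / (2 * dx) * (f$FQ[i + 1L] - f$FQ[i]) +
    dt / 4 * (sQ[i] + sQ[i + 1L])
  if (any(Ah <= 0)) stop("negative area in half step (CFL too aggressive?)", call. = FALSE)
  fh <- fp_hemo_flux(Ah, Qh, A0, beta, rho)
  j <- 2:(n - 1L)
  An <- A; Qn <- Q
  An[j] <- A[j] - dt / dx * (fh$FA[j] - fh$FA[j - 1L])
  Qn[j] <- Q[j] - dt / dx * (fh$FQ[j] - fh$FQ[j - 1L]) + dt * sQ[j]
  if (closed_left) {
    An[1L] <- A[1L] - 2 * dt / dx * fh$FA[1L]
    Qn[1L] <- 0
  }
  if (closed_right) {
    An[n] <- A[n] + 2 * dt / dx * fh$FA[n - 1L]
    Qn[n] <- 0
  }
  list(A = An, Q = Qn)
}

# characteristic extrapolation: invariant leaving the domain at a segment
# end, traced back along its characteristic from the old time level
fp_outgoing_invariant <- function(A, Q, seg_A0, seg_beta, rho, dx, dt, end) {
  n <- length(A)
  inv <- riemann_invariants(A, Q, seg_A0, seg_beta, rho)
  c_ <- wave_speed(A, seg_A0, seg_beta, rho)
  u <- Q / A
  if (end == "right") {  # W+ travels at u + c towards the right end
    s <- u[n] + c_[n]
    xi <- max(0, min(n - 1, (n - 1) - s * dt / dx))
    w <- inv$Wf
  } else {               # W- travels at u - c (< 0) towards the left end
    s <- u[1L] - c_[1L]
    xi <- max(0, min(n - 1, -s * dt / dx))
    w <- inv$Wb
  }
  i0 <- floor(xi); fr <- xi - i0
  w[i0 + 1L] * (1 - fr) + w[min(n, i0 + 2L)] * fr
}

# impose prescribed inflow at a segment's left end: solve for A such that
# Q_in/A - 4 (c(A) - c0) = Wb_extrapolated
fp_inlet_state <- function(Q_in, Wb, A0, beta, rho, A_guess) {
  c0 <- wave_speed(A0, A0, beta, rho)
  k <- sqrt(beta / (2 * rho * A0))
  g <- function(A) Q_in / A - 4 * (k * A^0.25 - c0) - Wb
  lo <- 1e-8 * A0; hi <- 1e4 * A0
  A <- tryCatch(stats::uniroot(g, c(lo, hi), tol = 1e-14)$root,
                error = function(e) stop("inlet characteristic solve failed", call. = FALSE))
  list(A = A, Q = Q_in)
}

# junction solve: unknowns (A_i, u_i) for every adjoining segment end;
# equations: outgoing invariant of each segment + mass balance + continuity
# of total pressure p + rho u^2 / 2. Reuses the package Newton solver.
fp_junction_solve <- function(prob, junction, Anew, Qnew, dt) {
  net <- prob$network
  segs <- junction
  m <- length(segs)
  A0s <- net$segments$A0[abs(segs)]
  betas <- net$segments$beta[abs(segs)]
  winv <- numeric(m); ends <- character(m)
  x0 <- numeric(2L * m)
  for (i in seq_len(m)) {
    s <- abs(segs[i])
    end <- if (segs[i] > 0) "right" else "left"
    ends[i] <- end
    winv[i] <- fp_outgoing_invariant(prob$A[[s]], prob$Q[[s]], A0s[i], betas[i],
                                     prob$rho, net$segments$dx[s], dt, end)
    n <- length(prob$A[[s]])
    j <- if (end == "right") n else 1L
    x0[2L * i - 1L] <- prob$A[[s]][j]
    x0[2L * i] <- prob$Q[[s]][j] / prob$A[[s]][j]
  }
  rho <- prob$rho
  resid <- function(x) {
    A <- x[seq(1L, 2L * m, by = 2L)]
    u <- x[seq(2L, 2L * m, by = 2L)]
    if (any(A <= 0)) return(rep(1e6, 2L * m))
    r <- numeric(2L * m)
    cs <- sqrt(betas / (2 * rho * A0s)) * A^0.25
    c0s <- sqrt(betas / (2 * rho * A0s)) * A0s^0.25
    # outgoing invariant of each segment
    for (i in seq_len(m)) {
      r[i] <- if (ends[i] == "right") u[i] + 4 * (cs[i] - c0s[i]) - winv[i]
              else                    u[i] - 4 * (cs[i] - c0s[i]) - winv[i]
    }
    # mass balance: flow into the junction equals flow out
    sgn <- ifelse(ends == "right", 1, -1)
    r[m + 1L] <- sum(sgn * A * u)
    # total pressure continuity relative to the first segment
    pt <- tube_pressure(A, A0s, betas, prob$p_ext) + 0.5 * rho * u^2
    if (m > 1L) r[(m + 2L):(2L * m)] <- pt[-1L] - pt[1L]
    r
  }
  sol <- newton_solve(resid, x0, tol = 1e-11, max_iter = 60L)
  for (i in seq_len(m)) {
    s <- abs(segs[i])
    n <- length(Anew[[s]])
    j <- if (ends[i] == "right") n else 1L
    Anew[[s]][j] <- sol$x[2L * i - 1L]
    Qnew[[s]][j] <- sol$x[2L * i - 1L] * sol$x[2L * i]
  }
  list(A = Anew, Q = Qnew)
}

#' Advance the 1D network one step (no 0D coupling)
#'
#' Interior points advance by two-step Lax-Wendroff; the inlet imposes the
#' prescribed flow through the backward invariant; junction ends are matched
#' by a characteristic Newton solve; outlet ends take a prescribed pressure
#' (`outlet_P`) through the forward invariant, or are closed (mirrored
#' ghost) when the problem has neither RCR outlets nor `outlet_P`.
#'
#' @param prob an `fp_hemo_problem`.
#' @param dt time step (must satisfy the CFL bound).
#' @param outlet_P numeric vector of prescribed outlet pressures (one per
#'   network outlet), or NULL.
#' @param commit write the new state into `prob` (default TRUE). With
#'   `commit = FALSE` the advanced state is only returned, which is what the
#'   coupling fixed-point loop uses for its trial steps.
#' @return invisibly, `list(A, Q, t)` of the advanced state.
#' @export
solve_1d_step <- function(prob, dt, outlet_P = NULL, commit = TRUE) {
  stopifnot(inherits(prob, "fp_hemo_problem"))
  dt_max <- cfl_dt(prob)
  if (dt > dt_max * (1 + 1e-12))
    stop(sprintf("CFL violation: dt=%.4g exceeds the stable limit %.4g (try dt <= %.4g)",
                 dt, dt_max, dt_max), call. = FALSE)
  net <- prob$network
  t <- prob$t
  junction_segments <- unlist(lapply(net$junctions, abs))
  Anew <- vector("list", net$n_segments)
  Qnew <- vector("list", net$n_segments)

  for (s in seq_len(net$n_segments)) {
    A0 <- net$segments$A0[s]; beta <- net$segments$beta[s]
    left_closed <- is.null(prob$inflow) && s == net$inlet
    right_closed <- is.null(prob$rcr) && is.null(outlet_P) && (s %in% net$outlets)
    up <- fp_richtmyer(prob$A[[s]], prob$Q[[s]], net$segments$dx[s], dt,
                       A0, beta, prob$rho, prob$K_R,
                       closed_left = left_closed, closed_right = right_closed)
    Anew[[s]] <- up$A; Qnew[[s]] <- up$Q
    if (any(up$A <= 0)) stop("negative area after 1D step", call. = FALSE)
  }

  # inlet (prescribed flow through the backward invariant)
  if (!is.null(prob$inflow)) {
    s <- net$inlet
    A0 <- net$segments$A0[s]; beta <- net$segments$beta[s]
    Wb <- fp_outgoing_invariant(prob$A[[s]], prob$Q[[s]], A0, beta, prob$rho,
                                net$segments$dx[s], dt, "left")
    st <- fp_inlet_state(prob$inflow(t + dt), Wb, A0, beta, prob$rho, Anew[[s]][1L])
    Anew[[s]][1L] <- st$A; Qnew[[s]][1L] <- st$Q
  }

  # outlets with prescribed pressure (from the Windkessel coupling)
  if (!is.null(outlet_P)) {
    for (k in seq_along(net$outlets)) {
      s <- net$outlets[k]
      A0 <- net$segments$A0[s]; beta <- net$segments$beta[s]
      Wf <- fp_outgoing_invariant(prob$A[[s]], prob$Q[[s]], A0, beta, prob$rho,
                                  net$segments$dx[s], dt, "right")
      Ab <- pressure_to_area(outlet_P[k], A0, beta, prob$p_ext)
      cb <- wave_speed(Ab, A0, beta, prob$rho)
      c0 <- wave_speed(A0, A0, beta, prob$rho)
      ub <- Wf - 4 * (cb - c0)
      n <- length(Anew[[s]])
      Anew[[s]][n] <- Ab; Qnew[[s]][n] <- ub * Ab
    }
  }

  # junctions
  for (jn in net$junctions) {
    up <- fp_junction_solve(prob, jn, Anew, Qnew, dt)
    Anew <- up$A; Qnew <- up$Q
  }

  if (commit) {
    prob$A <- Anew; prob$Q <- Qnew; prob$t <- t + dt
  }
  invisible(list(A = Anew, Q = Qnew, t = t + dt))
}

#' One coupled 1D-0D time step (fixed-point iteration to tolerance)
#'
#' Per step: (1) advance the 1D system with the current interface pressures
#' as outlet boundary conditions and extract the outlet flows; (2) integrate
#' each outlet's RCR Windkessel over the step with that flow as its forcing;
#' (3) read back the wanted interface pressure `P_in = Pc + Rp Q`;
#' (4) update the outlet boundary condition and repeat until the largest
#' interface-pressure change drops below the tolerance; then accept the step.
#'
#' @param prob an `fp_hemo_problem` with RCR outlets.
#' @param dt time step.
#' @return invisibly, the number of subiterations used (also appended to
#'   `prob$subiters`).
#' @export
couple_step <- function(prob, dt) {
  stopifnot(inherits(prob, "fp_hemo_problem"))
  if (is.null(prob$rcr)) stop("problem has no RCR outlets", call. = FALSE)
  net <- prob$network
  mf <- prob$wk_mf; ms <- prob$wk_ms; fld <- prob$wk_field
  q_comp <- get_component(fld, "bc", "Q_in")
  p_comp <- get_component(fld, "bc", "P_in")
  pc_saved <- mf_column(mf, "state", "Pc")
  substep <- prob$wk_substep %||% min(dt / 4, min(prob$rcr$Rd * prob$rcr$C) / 2)

  P_cur <- prob$P_interface
  trial <- NULL
  converged <- FALSE
  for (it in seq_len(prob$max_subiter)) {
    trial <- solve_1d_step(prob, dt, outlet_P = P_cur, commit = FALSE)
    Q_out <- vapply(seq_along(net$outlets), function(k) {
      s <- net$outlets[k]; trial$Q[[s]][length(trial$Q[[s]])]
    }, numeric(1L))
    # restart the Windkessel integration from the state at the step start
    fp_cell_write(mf$state_cells[["Pc"]], seq_len(mf$n_dof), pc_saved)
    set_all_dofs(q_comp, Q_out)
    integration_solve(ms, mf, prob$t, prob$t + dt, substep, "rk4")
    P_new <- p_comp$values
    err <- max(abs(P_new - P_cur))
    P_cur <- prob$relax * P_new + (1 - prob$relax) * P_cur
    if (err < prob$tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("1D-0D coupling did not converge in %d subiterations (residual %.3e)",
                 prob$max_subiter, err), call. = FALSE)
  prob$A <- trial$A; prob$Q <- trial$Q; prob$t <- trial$t
  prob$P_interface <- P_cur
  prob$subiters <- c(prob$subiters, it)
  invisible(it)
}

#' Run a hemodynamics simulation
#'
#' Steps the problem to `t_end` (coupled steps when RCR outlets are present,
#' plain 1D steps otherwise), recording probe time series.
#'
#' @param prob an `fp_hemo_problem`.
#' @param t_end end time.
#' @param dt step size; default 90% of the initial CFL limit, re-checked
#'   every step.
#' @param probes data.frame with columns `segment`, `index` (grid point);
#'   default: the outlet end of every outlet segment, else the inlet.
#' @return an object of class `fp_hemo_result` with `time`, `Q`, `P`, `A`
#'   matrices (rows = steps, columns = probes), `subiters`, and the final
#'   problem state.
#' @export
run_hemodynamics <- function(prob, t_end, dt = NULL, probes = NULL) {
  stopifnot(inherits(prob, "fp_hemo_problem"))
  net <- prob$network
  if (is.null(probes)) {
    probes <- if (length(net$outlets))
      data.frame(segment = net$outlets,
                 index = net$segments$n[net$outlets])
    else data.frame(segment = net$inlet, index = 1L)
  }
  if (is.null(dt)) dt <- 0.9 * cfl_dt(prob)
  np <- nrow(probes)
  nsteps <- ceiling(t_end / dt - 1e-12)
  Qm <- matrix(0, nsteps, np); Pm <- matrix(0, nsteps, np); Am <- matrix(0, nsteps, np)
  tv <- numeric(nsteps)
  for (k in seq_len(nsteps)) {
    h <- min(dt, t_end - prob$t)
    if (h <= 0) { k <- k - 1L; break }
    if (is.null(prob$rcr)) solve_1d_step(prob, h) else couple_step(prob, h)
    tv[k] <- prob$t
    for (p in seq_len(np)) {
      s <- probes$segment[p]; i <- probes$index[p]
      Am[k, p] <- prob$A[[s]][i]; Qm[k, p] <- prob$Q[[s]][i]
      Pm[k, p] <- tube_pressure(prob$A[[s]][i], net$segments$A0[s],
                                net$segments$beta[s], prob$p_ext)
    }
  }
  structure(list(time = tv[seq_len(k)], Q = Qm[seq_len(k), , drop = FALSE],
                 P = Pm[seq_len(k), , drop = FALSE], A = Am[seq_len(k), , drop = FALSE],
                 probes = probes, subiters = prob$subiters, problem = prob),
            class = "fp_hemo_result")
}

#' @exportS3Method base::print
print.fp_hemo_result <- function(x, ...) {
  cat(sprintf("<fp_hemo_result>: %d step(s) to t=%.4g, %d probe(s)%s\n",
              length(x$time), if (length(x$time)) max(x$time) else 0, nrow(x$probes),
              if (length(x$subiters)) sprintf("; subiterations max %d", max(x$subiters)) else ""))
  invisible(x)
}

#' Total vessel volume (mass) of the network state
#' @param prob an `fp_hemo_problem`.
#' @return sum over segments of the trapezoid-weighted integral of A
#'   (boundary nodes are half cells; conserved to round-off by the
#'   closed-end update).
#' @export
total_volume <- function(prob) {
  net <- prob$network
  sum(vapply(seq_len(net$n_segments), function(s) {
    A <- prob$A[[s]]; n <- length(A)
    net$segments$dx[s] * (sum(A) - 0.5 * A[1L] - 0.5 * A[n])
  }, numeric(1L)))
}

#' Standalone RCR Windkessel response to an imposed flow
#'
#' Integrates the shipped RCR model (through the compiled black box) under a
#' prescribed inflow and returns the capacitor and inlet pressure traces.
#'
#' @param params list/row with `Rp`, `Rd`, `C`, `P_out` and optionally `Pc0`.
#' @param Qfun function `t -> Q`.
#' @param t_end end time.
#' @param dt output step (the ODE advances with RK4 substeps of `dt`).
#' @return data.frame with columns `t`, `Q`, `Pc`, `P_in`.
#' @export
windkessel_response <- function(params, Qfun, t_end, dt) {
  env <- pm_environment()
  defn <- read_model(shipped_model_path("windkessel_rcr"))
  for (nm in c("Rp", "Rd", "C", "P_out"))
    defn <- pm_set_constant(defn, nm, params[[nm]])
  import_model(env, defn)
  flag_variable(env, 1L, "Q_in", known = TRUE)
  flag_variable(env, 1L, "P_in", wanted = TRUE)
  model <- instantiate(env)[[1L]]
  nt <- ceiling(t_end / dt - 1e-12)
  out <- data.frame(t = numeric(nt + 1L), Q = 0, Pc = 0, P_in = 0)
  st <- if (!is.null(params$Pc0)) params$Pc0 else model$initial_state
  t <- 0
  ev <- evaluate_model(model, t, st, Qfun(t))
  out[1L, ] <- c(t, Qfun(t), st, ev$wanted["P_in"])
  for (k in seq_len(nt)) {
    h <- min(dt, t_end - t)
    st <- step_rk4(model, t, st, Qfun(t), h)
    t <- t + h
    ev <- evaluate_model(model, t, st, Qfun(t))
    out[k + 1L, ] <- c(t, Qfun(t), st, ev$wanted["P_in"])
  }
  out
}

#' Built-in half-sine inflow pulse
#'
#' A stand-in aortic-root flow waveform: `Q_max sin(pi t / T_sys)` during
#' systole, 0 during the rest of each cycle of length `T_cycle`.
#'
#' @param Q_max peak flow.
#' @param T_sys systolic duration.
#' @param T_cycle cycle length.
#' @return function `t -> Q`.
#' @export
half_sine_inflow <- function(Q_max = 1, T_sys = 0.3, T_cycle = 0.8) {
  function(t) {
    tc <- t %% T_cycle
    ifelse(tc < T_sys, Q_max * sin(pi * tc / T_sys), 0)
  }
}
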