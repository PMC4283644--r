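---
title: "Coupling 0D point models into field simulations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling 0D point models into field simulations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldpoint)
```

# The problem

Much of computational physiology is built from two kinds of pieces. On one
side are *point models*: systems of ordinary differential and algebraic
equations describing processes at a spatial point — an ionic model of a
cardiac cell, a lumped three-element Windkessel standing in for a vascular
bed, a hyperelastic constitutive law at a material point. On the other side
are *field problems*: partial differential equations for quantities that
vary in space — transmembrane voltage over a tissue sheet, area and flow
along an arterial tree, stress through a deforming solid. Multi-scale
simulation means wiring the first kind into the second without hard-coding
any particular cell model, vascular bed model or material law into the
field solver.

`fieldpoint` implements that wiring. A point model is compiled into a
*black box* with a fixed contract,

```
evaluate(voi, states, known) -> (rates, wanted)
```

where `voi` is the value of the independent variable (usually time), `states`
is the state vector, `known` carries parameters supplied from outside, `rates`
are the state derivatives and `wanted` are the exported intermediates. The
field solver never sees the model's equations — it sees DOF-indexed value
stores, declarative maps between model variables and field components, and
two solvers (one that evaluates, one that integrates) that move data across
the boundary by a fixed transfer protocol.

# The model format and its compilation

Point models are written in a small line-oriented text format
(`const` / `init` / `ode` / `alg` / `independent` statements; see
`?parse_model`). Expressions allow arithmetic, comparisons, `exp`, `log`,
`sqrt`, `pow`, `abs` and a vectorised `piecewise`. Parsing rejects any other
function call, so a model file cannot execute arbitrary code; it also
rejects undefined symbols, duplicate definitions and cyclic algebraic
definitions (a topological order must exist and is computed at parse time).

Each model variable can be flagged *known* (its value is supplied from a
field) and/or *wanted* (its value is exported to a field). On import, all
state variables and the independent variable are flagged known and wanted;
nothing else is. At instantiation:

* unflagged constants are substituted numerically into every expression
  ("baked"), so they cost nothing at run time and cannot drift from the
  model file;
* flagged-known constants form the `known` input vector, in declaration
  order;
* flagged-wanted intermediates form the `wanted` output vector, in
  declaration order;
* the expressions are assembled into a single generated R function whose
  body unpacks state and known columns into locals and evaluates the
  algebraics in topological order. Because every permitted operation is
  elementwise, the same generated function evaluates one instance or a
  whole batch (a matrix with one row per DOF) — this is what makes a few
  hundred thousand model evaluations per simulation practical in R, and it
  is the natural hook for per-DOF parallelism, since instances at different
  DOFs never interact.

Two interpretation decisions were open and are fixed as follows. *Knowns
are restricted to constants*: a state enters through the state vector and an
intermediate is always computed inside the box, so flagging either "known"
would create two sources of truth for one value. *A state may be both
integrated and fed from a field*: the transfer protocol resolves ownership —
`transfer_in` overwrites the stored state at the start of each solve, the
integrator owns it during the solve, `transfer_out` publishes it afterwards.
Transfers happen exactly once before and once after each solver execution,
not at every substep; within a multi-substep integration the known inputs
are therefore held at their values from the start of the solve.

# Fields, DOF patterns and maps

A field holds variables, a variable holds components, and each component
has a DOF structure: `constant` (one value for the whole domain), `element`,
`node`, `gauss_point` (2×2 tensor points), or `data_point` (user-supplied
locations). Structured 2D meshes use bilinear Lagrange elements with
row-major node numbering from the bottom-left corner and element-local
coordinates in the unit square.

A *map set* binds model variables to field components. Deriving where model
instances live is mechanical: every mapped component exposes its DOF
locations, and the first map's locations become the DOF pattern. All other
mapped components must have DOFs at the same locations — compared with an
absolute tolerance of 1e-12, chosen far below any mesh spacing a user would
employ but above accumulated floating-point noise in coordinate
construction. Components may order their DOFs differently; a per-map
permutation is derived by location matching. One variable may be the target
of at most one map per direction, which keeps transfers deterministic
(fan-out from one component to several models remains possible).

The per-DOF model instances are backed by four structures over the pattern:
an integer *models* selector (0 disables a DOF entirely — its rows freeze),
and *state*, *parameters* and *intermediates* stores with one column per
model vector slot. With several imported models the column layout is the
union of the models' variable names, with `NA` sentinels in slots unused by
the model active at a DOF; this favours clarity over the alternative of
merging models into one switch-laden definition, at a known cost in storage
contiguity. When a mapped component's DOF ordering coincides with the
pattern, the component's store can directly back the column
(`shared = TRUE`): transfer becomes the identity, and the test suite holds
shared and copy modes to within 1e-14 of each other over whole simulations.
A shared column whose variable is fed *from* a field keeps the field's
content at creation instead of the model default, which is exactly what
copy mode produces after its first `transfer_in`.

# Solvers and control loops

The *integration solver* advances every active DOF's model over a window
with explicit substeps (forward Euler or classical RK4; the last substep is
truncated to land exactly on the stop time), then recomputes intermediates
at the stop time. The *evaluation solver* performs a single evaluation per
DOF and leaves states untouched, which makes it idempotent. Both are
wrapped in the transfer protocol. Adaptive and implicit integrators are
deliberately out: the shipped models are non-stiff at their documented
substeps, and fixed-step explicit schemes keep every run bit-reproducible.

Control loops nest: a time loop either contains child loops (whose windows
tile the parent step; a child step that does not divide the parent's is
rejected at construction) or a list of solvers executed in order. Execution
produces a trace of (loop, time, solver) tuples that the tests assert on.

The Newton solver completes the set: central finite-difference Jacobian
with relative perturbation 1e-7 (about the square root of double precision
rounded toward robustness), convergence on the residual infinity norm, and
a list of *linked* solvers executed before every residual evaluation. That
linking is the mechanism by which a constitutive evaluation solver runs
inside a nonlinear solve without the residual ever calling the material law
directly.

# Application 1: monodomain electrophysiology

The monodomain equation χCₘ ∂V/∂t = ∇·(σ∇V) − χI_ion + I_stim is split per
time step (Godunov splitting): first the reaction — an integration solve of
the ionic model at every node, with V a state mapped both directions and
the stimulus current a known input — then one implicit-Euler diffusion
solve with bilinear FEM (consistent mass matrix, no-flux boundaries, sparse
Cholesky factorisation computed once and reused). Because the stiffness
matrix has zero row sums, the diffusion step conserves the discrete
integral 1ᵀMV to round-off; the suite asserts 1e-10 per step and observes
~1e-16.

Defaults (all configurable): 25×25 elements on a 10×10 mm sheet,
σ = 0.1 mS/mm, χ = 140 /mm, Cₘ = 0.01 µF/mm², dt_pde = 0.1 ms,
dt_ode = 0.01 ms, t_end = 20 ms. The Hodgkin–Huxley 1952 membrane model is
the default cell model; it exposes its sodium conductance gNa as a known
parameter, so conductance experiments (uniform multipliers, or a radial
ramp from 100% at the bottom-left node to 300% at the top-right) need no
solver changes. Its shipped initial state is the quiescent equilibrium
obtained by root-finding on an independently written right-hand side, so a
non-stimulated sheet stays at rest to solver precision. The stimulus — the
leftmost half of the bottom node row, 100 µA/cm² for 1 ms — is strong
enough to launch a propagating wave against the diffusive load of the
sheet; 1 µA/cm² is comfortably subthreshold and the tests verify nothing
activates at that amplitude. Activation time at a node is the first upward
crossing of 0 mV, linearly interpolated between PDE steps; conduction
velocity is probe distance over activation-time difference, with default
probes on the bottom row beyond the stimulated half. FitzHugh–Nagumo ships
alongside for fast smooth tests; the splitting-order study uses it (12×12
mesh, RK4 substeps at 0.0025 so reaction error is negligible, PDE steps
0.2/0.1/0.05) and measures first-order self-convergence, as expected for
Godunov splitting.

# Application 2: 1D network hemodynamics with RCR outlets

The 1D flow system is solved in conservation form — ∂A/∂t + ∂Q/∂x = 0 and
∂Q/∂t + ∂(Q²/A + B(A))/∂x = −K_R Q/A with B(A) = β A^{3/2}/(3ρA₀) — under
the elastic tube law p = p_ext + β(√A − √A₀)/A₀ and a flat velocity profile.
The wave speed is c = √(β/(2ρA₀)) A^{1/4} and the Riemann invariants are
W± = u ± 4(c − c₀). Interior points advance by the two-step
(Richtmyer) Lax–Wendroff scheme under a CFL guard (default CFL number 0.8;
an oversized step is an error that reports the stable limit). Boundary and
junction points are set by characteristic matching: the invariant leaving
the domain is traced back along its characteristic from the previous time
level; the incoming one is fixed by the boundary condition (prescribed
inflow at the inlet; pressure-derived area at Windkessel outlets). Closed
ends are handled as conservative half cells with zero wall mass flux and
u = 0, which makes the trapezoid-weighted total volume telescope exactly —
the closed-vessel conservation check passes at round-off, far inside its
1e-8 band. Junctions impose mass balance and continuity of total pressure
p + ρu²/2, solved together with each adjoining segment's outgoing invariant
by the package's own Newton solver at tolerance 1e-11; a symmetric
bifurcation therefore splits flow identically to machine precision.

Each terminal outlet carries an RCR Windkessel point model
(C·dPc/dt = Q_in − (Pc − P_out)/R_d, exported P_in = Pc + R_p·Q_in), run
through exactly the same map/transfer machinery as the tissue models, on a
one-DOF-per-outlet pattern. Per time step the 1D and 0D sides iterate to a
fixed point: the trial 1D step's outlet flow forces the Windkessel over the
step (restarted from the step's initial capacitor state each subiteration),
the returned pressure updates the outlet boundary condition, and the loop
stops when the largest interface-pressure change falls below the tolerance
(default 1e-6). The update can be under-relaxed; the default factor is 1.
Under-relaxation matters when the instantaneous load slope
(R_p + R_d in the stiff, low-compliance limit) exceeds the vessel's
characteristic impedance ρc/A — the fixed-point gain is then above one and
a factor of about 0.5 restores contraction. The shipped fixtures
(symmetric bifurcation, three-generation tree with seven segments and four
outlets) use wall stiffnesses giving pulse-wave transit times well inside
one inflow cycle, so the outlets are genuinely loaded during a run; the
built-in half-sine inflow pulse is a declared stand-in waveform, not data.

# Application 3: plug-in constitutive laws

The incompressible Mooney–Rivlin law on the homogeneous uniaxial path
(λ_r = λ_θ = λ^{−1/2}, lateral faces traction-free so the hydrostatic
pressure is eliminated analytically) has the closed-form axial Cauchy
stress σ_zz = 2(λ² − 1/λ)(c₁ + c₂/λ) from W = c₁(I₁−3) + c₂(I₂−3). The
shipped model file computes σ_zz, W and the Green–Lagrange strain
components of the same path (the strain measure in tensor-style maps is
taken to be Green–Lagrange; nothing in the uniaxial driver depends on this
choice). The constitutive evaluation runs through the field-map route — a
stretch field in, a stress field out, one evaluation solver — and the tests
hold that route to within 1e-14 of the closed form, with a neo-Hookean file
swapped in to demonstrate that changing the material law means changing a
model file, not solver code. Stress-controlled extension is solved by the
Newton solver with the evaluation solver linked into its residual; the
default constants are c₁ = 2, c₂ = 1 kPa (declared, not sourced from data).
Restricting to the homogeneous uniaxial path is a deliberate scope cut: it
exercises the linked-solver pattern in isolation, while full 3D finite
elasticity would add FEM machinery orthogonal to the coupling architecture.

# What the tests do and do not show

All inputs are generated in code: meshes and networks from constructors,
model files from the shipped suite, waveforms from closed forms. The
fixtures are deliberately idealised — isotropic conductivity, frictionless
or Poiseuille-friction vessels, symmetric junction geometry, noiseless
parameters — so passing tests demonstrate the correctness of the coupling
machinery and the numerics under clean conditions, not fidelity to any
particular physiological dataset. Problem sizes in the test and acceptance
runs (the 25×25 monodomain sheet at 20 ms; the 12×12 splitting study; the
51-point vessels; 100-point oracle sweeps) were chosen as the smallest
sizes at which each property is cleanly measurable, and are stated in the
configurations themselves. The core solvers contain no randomness; the only
random numbers anywhere are the oracle sample points in the tests and
acceptance script, under a caller-supplied seed.

Known limitations: single-process execution (the ghost-DOF update hook is a
no-op kept for call-sequence fidelity); explicit fixed-step ODE integration
only, so stiff cell models would need small substeps; one value DOF per
node (no derivative DOFs, no higher-order bases); units on model constants
are carried as annotations but never checked or converted; the 1D blood
flow closure (tube law, flat profile, friction constant) is one standard
choice among several, and results near shock-like regimes inherit
Lax–Wendroff's dispersive oscillations.
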