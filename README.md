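# fieldpoint

Coupling 0D biophysical point models into spatial field simulations.

Physiological models are routinely assembled from two kinds of pieces:
zero-dimensional "point models" — ODE/algebraic systems at a conceptual
point in space, such as an ionic cell model, a lumped RCR Windkessel, or a
hyperelastic constitutive law — and spatial field problems such as tissue
electrical propagation, 1D arterial blood flow, or solid mechanics.
`fieldpoint` is an R implementation of the architecture that couples them
generically:

* **Point models** are written in a small declarative text format
  (`const` / `init` / `ode` / `alg` statements) and compiled into black
  boxes with the standard contract
  `evaluate(voi, states, known) -> (rates, wanted)`. Variables are flagged
  *known* (supplied from a field) and/or *wanted* (exported to a field);
  unflagged constants are baked into the compiled code.
* **Fields** hold spatial quantities as hierarchies of variables and
  components, each component with a DOF structure (constant, element, node,
  Gauss point, data point) and a value store.
* **Maps** bind model variables to field components. The mapped components'
  DOF locations define the *DOF pattern* — conceptually one model instance
  per DOF — and are checked for spatial compatibility (1e-12). Four backing
  structures (models / state / parameters / intermediates) store the
  per-DOF model data; an integer models field selects which model runs at
  each DOF, with 0 disabling it. Matching patterns can share storage with
  the mapped fields outright (zero-copy transfer).
* **Solvers** operate inside nested control loops: an *evaluation solver*
  (one evaluate per DOF) and an *integration solver* (explicit Euler/RK4
  substeps per DOF over a time window), both wrapped in a
  transfer-in / solve / transfer-out protocol, plus a Newton solver whose
  residual can execute *linked* solvers — the pattern used to evaluate
  constitutive laws inside a nonlinear solve.

Three reference applications exercise the architecture end to end:

1. **Monodomain electrophysiology** — χCₘ∂V/∂t = ∇·(σ∇V) − χI_ion + I_stim
   on a 2D sheet, Godunov operator splitting (reaction via the integration
   solver with a plug-in Hodgkin–Huxley 1952 or FitzHugh–Nagumo cell model;
   diffusion via implicit-Euler bilinear FEM), with spatially varying
   sodium conductance gNa mapped from a field.
2. **1D–0D hemodynamics** — conservation-form area/flow equations under an
   elastic tube law (wave speed c = √(β/2ρA₀)·A^¼, Riemann invariants
   W± = u ± 4(c − c₀)), two-step Lax–Wendroff interiors, characteristic
   boundaries and junctions, and RCR Windkessel outlet models iterated to a
   per-step fixed point on the interface pressure.
3. **Uniaxial hyperelastic extension** — the incompressible Mooney–Rivlin
   law σ_zz = 2(λ² − 1/λ)(c₁ + c₂/λ) as a plug-in algebraic point model,
   with stress-controlled stretch recovered by Newton + linked evaluation
   solver.

## Worked example

Compile the shipped Hodgkin–Huxley model, check its rest state, run the
standard monodomain experiment with doubled sodium conductance, and measure
the conduction velocity:

```r
library(fieldpoint)

env <- pm_environment()
import_model(env, read_model(shipped_model_path("hodgkin_huxley_1952")))
flag_variable(env, 1, "gNa", known = TRUE)    # supplied per node from a field
flag_variable(env, 1, "i_Na", wanted = TRUE)  # exported sodium current
model <- instantiate(env)[[1]]
model
#> <pm_compiled 'hodgkin_huxley_1952'>: 4 state(s) [V,m,h,n], 1 known [gNa], 1 wanted [i_Na]

r <- evaluate_model(model, 0, model$initial_state, model$default_known)
max(abs(r$rates))      # the shipped initial state is the resting equilibrium
#> [1] 7.761347e-12
r$wanted               # resting sodium current (uA/cm^2)
#>      i_Na
#> -1.221323

res <- run_monodomain(monodomain_config(gna_multiplier = 2))
res
#> <fp_monodomain_result>: hodgkin_huxley_1952 on 25x25 elements, t_end=20 ms;
#>   676/676 nodes activated; diffusion conservation (max rel per step) 2.72e-16

pr <- cv_probes(res$mesh)                     # two bottom-row probe nodes
conduction_velocity(res, pr[1], pr[2])        # mm/ms
#> [1] 1.53206
```

At the normal conductance the same measurement gives 0.573 mm/ms, and at
three times normal 7.70 mm/ms — the activation wavefront speeds up with
gNa. Stress-controlled extension through the linked Newton solver:

```r
str(solve_extension(10.5, c1 = 1, c2 = 1))
#> List of 3
#>  $ lambda       : num 2
#>  $ iterations   : int 4
#>  $ residual_norm: num 2.59e-13
```

which inverts σ_zz = 2(λ² − 1/λ)(c₁ + c₂/λ) = 10.5 back to λ = 2.

A command-line wrapper is installed under `exec/`:

```sh
fieldpoint run-monodomain   --config run.yaml --out outdir/
fieldpoint run-hemodynamics --config run.yaml --out outdir/
fieldpoint run-extension    --config run.yaml --out outdir/
fieldpoint fixtures --name bifurcation_network --out dir/
fieldpoint validate-model --model file.pm
```

Example configurations live in `inst/extdata/examples/`; outputs are CSV
tables, legacy-VTK field snapshots and a JSON run manifest (config hash,
package version, wall time), byte-stable across reruns of the same config.

## Layout

```
R/                  pointmodels, fields, coupling, solvers,
                    monodomain, hemodynamics, elasticity, cli_io
inst/extdata/models/    the five shipped .pm point-model files
inst/extdata/examples/  example YAML run configurations
tests/testthat/     unit, property and acceptance suites
scripts/acceptance.R    headline-quantity reproduction script
vignettes/          methods vignette (model, numerics, design choices)
exec/fieldpoint     command-line entry point
```
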