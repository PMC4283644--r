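Package: fieldpoint
Title: Coupling 0D Biophysical Point Models into Spatial Field Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A field-based data model for multi-scale physiological simulation
    in which zero-dimensional differential-algebraic "point models" (ionic cell
    models, lumped-parameter Windkessel models, hyperelastic constitutive laws)
    are compiled to black boxes and instantiated at the degrees of freedom of
    spatial fields. Provides a declarative text format for point models with
    known/wanted variable flagging, field/variable/component hierarchies with
    per-DOF value stores, maps between model variables and field components with
    DOF-pattern compatibility checking, evaluation and integration solvers
    inside nested control loops, and three reference applications: operator-split
    monodomain cardiac electrophysiology, 1D arterial hemodynamics iteratively
    coupled to RCR Windkessel outlets through Riemann invariants, and uniaxial
    hyperelastic extension with a plug-in constitutive law linked to a Newton
    solver.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
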