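Package: vlscreen
Title: Virtual-Ligand Screening and Optimization for Phosphine Ligand Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the virtual-ligand (VL) framework for quantitative
    ligand selection in transition-metal catalysis. A virtual ligand is a
    PCl3 model whose electronic and steric character is tuned by three
    penalty-function parameters (equilibrium P-Cl distance r0 and ovoid
    half-axes a1, b1). The package links real phosphine ligands to this
    low-dimensional parameter space through a PCA descriptor space built
    from ligand dissociation energies, projects descriptor vectors onto the
    virtual-ligand surface by conjugate-gradient least squares, optimizes
    VL parameters against a reaction objective with a smooth barrier
    (VLAO), and predicts the performance of every ligand in a database from
    a single surrogate model: a second-order Taylor expansion with
    positive-semidefinite-clipped Hessian, an inverse-square-distance
    weighted average of Taylor expansions along the optimization
    trajectory, or the objective itself. Candidate ligands are ranked after
    reliability filtering on the projection residual l_min and the
    range-normalized parameter deviation. A smooth synthetic analytic
    energy backend stands in for quantum-chemistry calculations so the full
    pipeline can be built and tested on the desktop.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
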