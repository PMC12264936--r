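---
title: "Methods: virtual-ligand screening with vlscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual-ligand screening with vlscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlscreen)
```

## The model

A virtual ligand (VL) is a PCl3 stand-in for a phosphine PR3 whose
electronic and steric character is controlled by penalty functions
rather than by chemical structure. Three parameters are optimized:

| parameter | role | unit | accessible range (default) |
|---|---|---|---|
| `r0` | equilibrium P–Cl distance of the keep potential (electronic) | Å | 1.3–1.9 |
| `a1` | ovoid width half-axis of the steric LJ potential | Å | 2.0–3.5 |
| `b1` | ovoid thickness half-axis | Å | 1.5–3.0 |

The remaining settings are held fixed: the Cl–P–Cl equilibrium angle
`phi0` = 65°, the ovoid lengths `c1` = `c2` = 3.0 Å, the ovoid–P
offset `d` = 3.0 Å, and in symmetric-substituent mode the mirror
half-axes `a2` = `a1`, `b2` = `b1`. Force constants default to
`kKeep` = 100 kcal/mol/Å² and `kAngle` = 0.1 kcal/mol/deg² — stiff
enough to hold the PCl3 core near its equilibrium in the analytic test
surfaces while leaving the angle term soft relative to the bond term —
and the ovoid LJ well depth is 0.1 kcal/mol, a typical nonbonded
contact energy. All are configurable through `fixedVLSettings()`.

Two maps define the framework. The descriptor map `G` sends a
parameter point **p** to the m = 16 ligand dissociation energies
(after a frozen PCA transform, see below); its image is an
n-dimensional surface in descriptor space. The objective map `F` sends
**p** to the scalar performance y (kcal/mol). Predicting a real
ligand's performance is the composition: project its descriptor vector
onto the surface (`H`, giving **p** and the residual `l_min`), then
evaluate a surrogate of `F` at that **p**.

Two assumptions are inherited from the underlying theory: `F` and `G`
are smooth in **p** (satisfied by construction for the analytic
backend; satisfied for quantum-chemical energies because VL penalty
energies are differentiable in the parameters), and the descriptor
components are uncorrelated (enforced exactly by the PCA transform).

## The ovoid Lennard-Jones form

The concrete closed-surface expression of the steric term is a design
choice of this package. For each P–Cl* axis an ovoid frame is built
from the axis direction and the lone-pair axis (the negative sum of
the three P–Cl* unit vectors); an environment atom at local
coordinates (t, xa, xb) has the scaled radius

q = sqrt( (t/c)² + (xa/a)² + (xb/b)² ),

which equals 1 on the ovoid surface, and contributes
ε (q⁻¹² − 2 q⁻⁶). This is smooth everywhere except the ovoid center
(flagged as a singular-distance error), vanishes as atoms recede, has
its minimum exactly on the surface, and is mirror-symmetric when
`a2 = a1`, `b2 = b1`. The form is isolated in `ovoidLJEnergy()` so an
alternative ovoid definition can be swapped in without touching the
rest of the package; all coordinate and parameter gradients are
analytic, including the chain rule through the frame vectors, and are
verified against central finite differences at 1e-5 relative
tolerance.

## Descriptor space and the database

Raw descriptors are dissociation energies over a fixed fragment set
(16 by default). PCA is performed on the covariance of the raw
energies — no variance standardization, since the energies share one
unit and the transform should not reweight fragments — and all m
components are retained. The loading matrix is orthonormal, so the
transform is an isometry: projection residuals are identical in raw
and score coordinates, and the model is frozen with the database so
every later projection uses the same transform. Zero-variance
components (rank-deficient tables) are flagged, not dropped.

The packaged database (`ligandDatabase()`) holds the projected
parameters and residuals of 21 monodentate phosphines; it is the
fixture all filter-count results are computed from.

## Projection and VLAO numerics

Both the projection and the VLAO optimization use the same
conjugate-gradient engine: Polak–Ribière(+) directions with a restart
on non-descent, Armijo backtracking (c = 1e-4, shrink 0.5) with the
initial step carried over from the previous iteration's decrease rate,
and rejection of steps into nonpositive parameter components (the
parameters are physical lengths). The projection minimizes l², not l,
avoiding the non-differentiable point at l = 0; convergence is
declared at a gradient norm of 1e-8 (projection) or 1e-6 (VLAO), with
a 500-iteration cap and a `converged` flag rather than an error on
non-convergence. On warped surfaces the projection multi-starts (5
seeded restarts around the initial point (1.6, 3.0, 2.0) Å) and keeps
the best minimum; ties are broken by distance to the initial point,
then lexicographically, so results are deterministic and independent
of restart order. Bounds are not enforced during projection — the
barrier belongs to VLAO only.

The VLAO barrier is a smooth polynomial wall: zero on the central 90%
of each accessible range and growing as the fourth power of the
normalized excess with stiffness 50 kcal/mol, so it is C³, already
positive at the bounds, and leaves an interior plateau where the
objective alone drives the optimization. Because the optimum of
y + B is not a stationary point of y, the gradient and Hessian used by
the surrogates are those of the *uncorrected* objective, and the
Hessian (obtained by central differences of backend gradients, step
1e-4) can carry negative eigenvalues; these are clipped to exactly
zero — positive semidefinite, not definite — which is the
Frobenius-nearest PSD matrix with the same eigenvectors.

## Surrogates

`taylorEval()` is the quadratic model around p*. `weightedEval()`
averages the member Taylor values with weights 1/‖Δp′‖², where ‖Δp′‖
is the range-normalized deviation (the same metric as the reliability
filter); a query within 1e-8 normalized units of a member returns that
member's value directly, which is the exact singular-weight limit.
Whether the trajectory members should carry clipped Hessians is
genuinely open; the package clips each member by default, consistent
with the single-point surrogate, and exposes `clip = FALSE` for the
alternative. All accepted VLAO iterates become members by default,
with an optional `maxMembers` subsample for long trajectories. Direct
mode evaluates the backend itself and is the accuracy ceiling: on the
synthetic test surface the mean absolute prediction error over a
ligand set is ordered direct ≤ weighted ≤ single-point Taylor.

## The synthetic backend: what it does and does not emulate

The generator supplies what a quantum-chemistry engine would:
a smooth objective and a smooth descriptor map with exact gradients.
The objective is a positive-definite quadratic (curvatures 2–10
kcal/mol/Å², minimum drawn inside the accessible box) plus a Gaussian
bump of amplitude 10% of the quadratic range — enough anharmonicity
that Taylor-surrogate error grows with distance, which is the regime
the trajectory-weighted surrogate is designed for. Descriptor energies
are drawn at realistic magnitudes (offsets ~30 ± 10 kcal/mol,
sensitivities ~3 kcal/mol/Å); `warp = 0` gives the exactly affine
surface used as the closed-form projection oracle, small positive
warp gives the curved case checked against a dense grid search.
Synthetic "real" ligands are placed at G(pTrue) plus an offset of
magnitude δ strictly orthogonal to the local tangent space — the
component a VL cannot represent — with δ drawn from 0.5–3
kcal/mol-scale units to match the spread of residuals observed across
real monodentate phosphines (≈1.1–4.6).

What the generator does not emulate: functional-group-specific
attractive interactions (ionic, π–π, CH/π) between ligand and
substrate, multiple competing local minima of realistic objectives,
DFT-level noise, or any actual chemistry of the 16 fragments. Passing
tests therefore demonstrate the correctness of the mathematical
pipeline — projection, surrogate construction, filtering, ranking —
not the chemical accuracy of VL predictions, which depends on the
quantum-chemical backend the framework is coupled to.

## Reliability filtering

Both thresholds are compared with strict inequalities (`l_min` below
its threshold *and* ‖Δp′‖ below its threshold); boundary ligands would
flip the reported counts, so the choice is documented and fixed. The
bounds in ‖Δp′‖ default to the VLAO barrier ranges — the deviation is
measured in the same units the optimization was confined to — and are
overridable. Rank ties are broken by smaller deviation, then id, so
reports are byte-reproducible.

## Problem sizes

The test suite runs the full synthetic pipeline at the study scale (21
ligands × 16 fragments, 3 parameters), the grid-search projection
oracle on a 2-parameter surface with a 0.01 Å grid, and the
finite-difference gradient checks on seeded random geometries with 4
environment atoms; the whole suite completes in under a minute on one
CPU.

## Known limitations

- The exact ovoid functional form and force constants of the original
  VL implementation are not reproduced here; the package's form is a
  documented, swappable stand-in, so absolute penalty energies are not
  comparable against that implementation.
- Projection is a local optimizer with multi-start, not a global
  method; on strongly multimodal descriptor surfaces the returned
  minimum may be local (the grid oracle in the tests covers mildly
  warped surfaces only).
- Reference points obtained by VLAO are local optima of y + B; a large
  ‖Δp′‖ can reflect a missed global optimum as well as Taylor error.
- A quantum-chemistry backend adapter is specified as an interface
  only (any function returning value and gradient); no DFT results are
  computed or reproduced by this package.
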