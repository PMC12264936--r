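# vlscreen

Quantitative selection of phosphine ligands for transition-metal
catalysis from a virtual-ligand (VL) surrogate model.

## The problem

Finding the ligand that maximizes (or minimizes) a reaction objective —
an activation barrier, a reaction energy, a selectivity — normally means
running expensive quantum-chemical calculations for every candidate.
The virtual-ligand strategy replaces the real ligand by a PCl3 model
whose electronic and steric character is set by three penalty-function
parameters **p** = (r0, a1, b1): the equilibrium P–Cl distance of a
harmonic *keep potential* (electronic effect) and the width/thickness
half-axes of an ovoid Lennard-Jones potential (steric effect). Because
the objective is differentiable in **p**, the optimal virtual ligand can
be found by gradient-driven optimization (VLAO). `vlscreen` implements
the mathematical framework that links this parameter space back to real
molecules, so that one optimization predicts the performance of every
ligand in a database.

## The method

For real ligands R and virtual ligands P, with y the objective and
**x** an m-dimensional descriptor vector (PCA scores of ligand
dissociation energies over a fixed set of m = 16 metal–fragment
complexes, so the components are exactly uncorrelated):

- **G**: p ↦ x, the descriptor map; its image G(P) is an n-dimensional
  surface in the m-dimensional descriptor space.
- **H**: x ↦ p, nearest-point projection onto G(P), computed by
  conjugate-gradient minimization of l(x, p)²; the residual l_min
  measures how well a real ligand is representable by a VL and is
  reaction-independent, so H(G(R)) is built once as a database.
- **VLAO**: minimize y + B(p) over p, where B is a smooth barrier
  confining p to a realistic range (defaults r0 1.3–1.9 Å,
  a1 2.0–3.5 Å, b1 1.5–3.0 Å), giving the reference point p*.
- **F̃**: second-order Taylor expansion of y around p* with the Hessian
  clipped to positive semidefiniteness; **F̂**: average of Taylor
  expansions at every VLAO iterate weighted by the inverse square of the
  range-normalized deviation ‖Δp′‖; or the objective itself (direct
  mode).
- **Ranking**: each database ligand is predicted at its p, filtered on
  the two reliability indices — l_min and
  ‖Δp′‖ = sqrt(Σᵢ ((pᵢ − p*ᵢ)/(pᵢ^Max − pᵢ^min))²) — with strict
  (l_min < 2.0, ‖Δp′‖ < 0.75) or loose (< 2.5, < 1.0) thresholds, and
  ranked by predicted objective.

A smooth synthetic analytic backend (positive-definite quadratic
objective plus a Gaussian bump; affine descriptor map plus optional
quadratic warp) stands in for the quantum-chemistry engine, so the full
pipeline runs and is tested on a desktop.

## Worked example

The packaged database holds the VL parameters and projection residuals
of 21 monodentate phosphines:

```r
library(vlscreen)
db <- ligandDatabase()
head(db, 3)
#>   id              name    r0    a1    b1 l_min
#> 1 L1 P(3;5-diCF3C6H3)3 1.685 4.307 1.225 3.968
#> 2 L2          P(C6F5)3 1.857 2.795 1.490 2.261
#> 3 L3          P(CCl3)3 1.966 2.995 2.119 3.330
```

Screening it around the VLAO optimum of a Pd(II) C–H activation
objective, p* = (1.35, 2.90, 1.62), the strict reliability filter keeps
six ligands:

```r
pStar <- c(1.35, 2.90, 1.62)
applyFilter(db, pStar, defaultBounds(), defaultFilters()$strict)[,
            c("id", "name", "l_min", "dp_norm")]
#>     id          name l_min   dp_norm
#> 7   L7          PEt3 1.419 0.2813941
#> 10 L10      P(NMe2)3 1.488 0.1890044
#> 11 L11       P(OMe)3 1.482 0.5475746
#> 12 L12          PPh3 1.744 0.3881015
#> 18 L18   P(p-FC6H4)3 1.863 0.4166389
#> 20 L20 P(p-MeOC6H4)3 1.840 0.2937724
```

These are the candidates whose predictions are trustworthy: small
l_min means the VL reproduces the ligand well, small ‖Δp′‖ means the
Taylor surrogate is evaluated close to its expansion point.

An end-to-end synthetic run — database build (dissociation table → PCA
→ projection), VLAO, trajectory-weighted surrogate, ranking:

```r
cfg <- list(seed = 11,
            backend = list(n = 3, m = 16, warp = 0, bumpFraction = 0.1),
            ligands = list(count = 21, deltaRange = c(0.5, 3)),
            bounds = list(lower = c(1.3, 2.0, 1.5),
                          upper = c(1.9, 3.5, 3.0)),
            surrogate = list(mode = "weighted"))
out <- runPipeline(cfg)
out$report
#> RankingReport (minimize): 21 ligands, p* = (1.782, 2.642, 2.150)
#>   strict   13 pass; top: L18, L6, L11
#>   loose    19 pass; top: L8, L18, L6
```

The report table carries, per ligand, the predicted objective, both
reliability indices, pass flags and within-filter ranks. A thin
command-line wrapper (`inst/scripts/vlscreen`) exposes `run`, `rank`
and `project` subcommands over the same functions.

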