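#' @import methods
NULL

#' Virtual-ligand parameter vector
#'
#' Holds the three tunable parameters of the virtual ligand: the
#' equilibrium P-Cl distance \code{r0} of the keep potential (electronic
#' character) and the ovoid half-axes \code{a1} (width) and \code{b1}
#' (thickness) of the steric Lennard-Jones penalty. All values in Angstrom.
#'
#' @slot r0 numeric(1), equilibrium P-Cl distance (Angstrom).
#' @slot a1 numeric(1), ovoid width half-axis (Angstrom).
#' @slot b1 numeric(1), ovoid thickness half-axis (Angstrom).
#' @exportClass VLParams
setClass("VLParams",
  representation(r0 = "numeric", a1 = "numeric", b1 = "numeric"))

setValidity("VLParams", function(object) {
  v <- c(object@r0, object@a1, object@b1)
  if (length(v) != 3L || !all(is.finite(v)))
    return("r0, a1, b1 must each be a single finite number")
  if (any(v <= 0))
    return("r0, a1, b1 must be strictly positive")
  TRUE
})

#' Fixed virtual-ligand settings
#'
#' Settings held constant during optimization: the equilibrium Cl-P-Cl
#' angle \code{phi0}, the remaining ovoid geometry parameters and the
#' harmonic force constants. In symmetric-substituent mode the mirror
#' half-axes a2, b2 are tied to a1, b1.
#'
#' @slot phi0 equilibrium Cl-P-Cl angle (degrees).
#' @slot a2,b2 mirror half-axes (Angstrom); \code{NA} means tied to a1, b1.
#' @slot c1,c2 ovoid length parameters along the P-Cl axis (Angstrom).
#' @slot d offset of the ovoid center from P along the axis (Angstrom).
#' @slot kKeep keep-potential force constant (kcal/mol/Angstrom^2).
#' @slot kAngle keep-angle force constant (kcal/mol/degree^2).
#' @slot epsLJ Lennard-Jones well depth of the ovoid potential (kcal/mol).
#' @slot symmetric logical; if TRUE, a2 = a1 and b2 = b1.
#' @exportClass FixedVLSettings
setClass("FixedVLSettings",
  representation(phi0 = "numeric", a2 = "numeric", b2 = "numeric",
                 c1 = "numeric", c2 = "numeric", d = "numeric",
                 kKeep = "numeric", kAngle = "numeric", epsLJ = "numeric",
                 symmetric = "logical"))

setValidity("FixedVLSettings", function(object) {
  sc <- c(object@phi0, object@c1, object@c2, object@d,
          object@kKeep, object@kAngle, object@epsLJ)
  if (!all(is.finite(sc)) || any(c(object@c1, object@c2, object@d) <= 0))
    return("phi0, c1, c2, d and force constants must be finite; lengths positive")
  if (!object@symmetric && (!is.finite(object@a2) || !is.finite(object@b2)))
    return("a2 and b2 must be given when symmetric = FALSE")
  TRUE
})

#' Parameter bounds
#'
#' Componentwise accessible range of the VL parameters, used by the VLAO
#' barrier function and by the range-normalized deviation metric.
#'
#' @slot lower,upper named numeric vectors, lower < upper componentwise.
#' @exportClass ParamBounds
setClass("ParamBounds",
  representation(lower = "numeric", upper = "numeric"))

setValidity("ParamBounds", function(object) {
  if (length(object@lower) != length(object@upper))
    return("lower and upper must have the same length")
  if (!all(is.finite(object@lower)) || !all(is.finite(object@upper)))
    return("bounds must be finite")
  if (any(object@upper - object@lower <= 0))
    return("upper must exceed lower componentwise (strictly positive width)")
  TRUE
})

#' Molecular geometry for the virtual-ligand penalty terms
#'
#' A set of atoms with designated phosphorus center, three Cl* atoms
#' (the virtual-ligand pseudo-substituents) and environment atoms that
#' feel the ovoid steric potential.
#'
#' @slot elements character vector of element symbols.
#' @slot coords numeric matrix (natoms x 3), Cartesian coordinates (Angstrom).
#' @slot pIndex integer(1), row index of the P atom.
#' @slot clIndices integer(3), row indices of the Cl* atoms.
#' @slot envIndices integer vector, row indices of environment atoms.
#' @exportClass MolecularGeometry
setClass("MolecularGeometry",
  representation(elements = "character", coords = "matrix",
                 pIndex = "integer", clIndices = "integer",
                 envIndices = "integer"))

setValidity("MolecularGeometry", function(object) {
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3L) return("coords must be an n x 3 matrix")
  if (length(object@elements) != n) return("elements length must match coords")
  if (!all(is.finite(object@coords))) return("coordinates must be finite")
  if (length(object@pIndex) != 1L) return("exactly one P index required")
  if (length(object@clIndices) != 3L) return("exactly three Cl* indices required")
  idx <- c(object@pIndex, object@clIndices, object@envIndices)
  if (any(idx < 1L | idx > n)) return("atom indices out of range")
  if (anyDuplicated(c(object@pIndex, object@clIndices)))
    return("P and Cl* indices must be distinct")
  TRUE
})

#' Synthetic analytic energy surface
#'
#' A smooth analytic stand-in for the quantum-chemical objective and
#' descriptor maps. The objective F is a positive-definite quadratic plus
#' an optional Gaussian bump; the descriptor map G is an affine map from
#' the n-dimensional parameter space into the m-dimensional energy space
#' plus an optional mild quadratic warp. Both are twice differentiable
#' with closed-form gradients.
#'
#' @slot n parameter dimension.
#' @slot m descriptor (fragment) dimension, m > n.
#' @slot p0 objective quadratic minimum (length n).
#' @slot A objective quadratic matrix (n x n, positive definite).
#' @slot f0 objective value offset (kcal/mol).
#' @slot bumpAmp,bumpCenter,bumpWidth Gaussian bump amplitude (kcal/mol),
#'   center (length n) and width (Angstrom).
#' @slot g0 descriptor offset (length m, kcal/mol).
#' @slot B descriptor linear map (m x n).
#' @slot warp quadratic warp amplitude (0 = exactly affine).
#' @slot warpMats list of m symmetric n x n warp matrices.
#' @slot bounds ParamBounds the surface is intended to be used on.
#' @slot seed integer seed the surface was drawn with.
#' @exportClass SyntheticSurface
setClass("SyntheticSurface",
  representation(n = "integer", m = "integer",
                 p0 = "numeric", A = "matrix", f0 = "numeric",
                 bumpAmp = "numeric", bumpCenter = "numeric",
                 bumpWidth = "numeric",
                 g0 = "numeric", B = "matrix", warp = "numeric", warpMats = "list",
                 bounds = "ParamBounds", seed = "integer"))

setValidity("SyntheticSurface", function(object) {
  if (object@m <= object@n) return("descriptor dimension m must exceed n")
  if (!all(dim(object@A) == object@n)) return("A must be n x n")
  if (!all(dim(object@B) == c(object@m, object@n))) return("B must be m x n")
  if (length(object@g0) != object@m) return("g0 must have length m")
  ev <- eigen(object@A, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return("A must be positive definite")
  if (object@warp != 0 && length(object@warpMats) != object@m)
    return("warpMats must hold one matrix per descriptor component")
  TRUE
})

#' Principal-component model of the dissociation-energy space
#'
#' Frozen PCA transform mapping raw dissociation energies to descriptor
#' scores. All m components are retained; the loading matrix is orthonormal
#' so the transform is an isometry of the energy space.
#'
#' @slot center column means of the training table (kcal/mol).
#' @slot rotation orthonormal loading matrix (m x m).
#' @slot sdev component standard deviations.
#' @slot zeroVariance logical vector flagging components with (numerically)
#'   zero variance in the training data.
#' @exportClass PCAModel
setClass("PCAModel",
  representation(center = "numeric", rotation = "matrix", sdev = "numeric",
                 zeroVariance = "logical"))

setValidity("PCAModel", function(object) {
  m <- length(object@center)
  if (!all(dim(object@rotation) == m)) return("rotation must be m x m")
  q <- crossprod(object@rotation)
  if (max(abs(q - diag(m))) > 1e-10) return("rotation must be orthonormal")
  TRUE
})

#' Result of projecting a descriptor vector onto the virtual-ligand surface
#'
#' @slot p projected VL parameters (length n).
#' @slot lMin Euclidean residual distance in descriptor space.
#' @slot iterations accepted conjugate-gradient iterations.
#' @slot converged logical convergence flag.
#' @slot trace matrix of accepted iterates (columns: parameters, then l^2).
#' @exportClass ProjectionResult
setClass("ProjectionResult",
  representation(p = "numeric", lMin = "numeric", iterations = "integer",
                 converged = "logical", trace = "matrix"))

setValidity("ProjectionResult", function(object) {
  if (length(object@lMin) != 1L || !is.finite(object@lMin) || object@lMin < 0)
    return("lMin must be a single nonnegative number")
  TRUE
})

#' Trajectory of a virtual-ligand-assisted optimization (VLAO) run
#'
#' Ordered accepted iterates of the barrier-corrected objective
#' minimization, with the uncorrected objective value and gradient at
#' each iterate. The trajectory is the input contract for the
#' trajectory-weighted surrogate.
#'
#' @slot params matrix of accepted iterates (k x n).
#' @slot values uncorrected objective values at each iterate (kcal/mol).
#' @slot gradients gradients of the uncorrected objective (k x n).
#' @slot penalized objective-plus-barrier values at each iterate.
#' @slot pStar final accepted iterate.
#' @slot fStar uncorrected objective at pStar.
#' @slot iterations number of accepted iterations.
#' @slot converged logical convergence flag.
#' @slot sense "minimize" or "maximize".
#' @exportClass VLAOTrajectory
setClass("VLAOTrajectory",
  representation(params = "matrix", values = "numeric", gradients = "matrix",
                 penalized = "numeric", pStar = "numeric", fStar = "numeric",
                 iterations = "integer", converged = "logical",
                 sense = "character"))

setValidity("VLAOTrajectory", function(object) {
  k <- nrow(object@params)
  if (length(object@values) != k || nrow(object@gradients) != k)
    return("values and gradients must align with params rows")
  if (!identical(unname(object@pStar), unname(object@params[k, ])))
    return("pStar must equal the last accepted iterate")
  if (!object@sense %in% c("minimize", "maximize"))
    return("sense must be 'minimize' or 'maximize'")
  TRUE
})

#' Second-order Taylor surrogate of the virtual-ligand objective
#'
#' Realizes the quadratic model f0 + g'(p - p*) + (p - p*)' Hc (p - p*)/2
#' around the reference point p*, with the Hessian clipped to be positive
#' semidefinite.
#'
#' @slot pStar reference point (length n).
#' @slot f0 objective value at pStar (kcal/mol).
#' @slot g gradient at pStar (length n).
#' @slot Hc clipped Hessian (n x n, symmetric PSD).
#' @exportClass TaylorSurrogate
setClass("TaylorSurrogate",
  representation(pStar = "numeric", f0 = "numeric", g = "numeric",
                 Hc = "matrix"))

setValidity("TaylorSurrogate", function(object) {
  n <- length(object@pStar)
  if (length(object@g) != n || !all(dim(object@Hc) == n))
    return("gradient and Hessian dimensions must match pStar")
  if (max(abs(object@Hc - t(object@Hc))) > 1e-8)
    return("Hc must be symmetric")
  ev <- eigen((object@Hc + t(object@Hc)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) < -1e-8) return("Hc must be positive semidefinite")
  TRUE
})

#' Trajectory-weighted surrogate
#'
#' A sequence of Taylor surrogates, one per retained VLAO trajectory
#' point, combined by inverse-square normalized-distance weighting.
#'
#' @slot members list of \linkS4class{TaylorSurrogate} objects.
#' @slot bounds \linkS4class{ParamBounds} defining the normalized metric.
#' @slot epsilon singularity guard for the weights (normalized units).
#' @exportClass TrajectorySurrogate
setClass("TrajectorySurrogate",
  representation(members = "list", bounds = "ParamBounds",
                 epsilon = "numeric"))

setValidity("TrajectorySurrogate", function(object) {
  if (length(object@members) < 1L)
    return("at least one trajectory member required")
  if (!all(vapply(object@members, is, logical(1), "TaylorSurrogate")))
    return("members must all be TaylorSurrogate objects")
  if (object@epsilon <= 0) return("epsilon must be positive")
  TRUE
})

#' Reliability filter specification
#'
#' Thresholds on the two reliability indices: the projection residual
#' l_min and the range-normalized parameter deviation. Ligands pass when
#' both indices are strictly below their thresholds.
#'
#' @slot lMinMax threshold on l_min.
#' @slot dpNormMax threshold on the normalized deviation.
#' @slot name label, e.g. "strict" or "loose".
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(lMinMax = "numeric", dpNormMax = "numeric",
                 name = "character"))

setValidity("FilterSpec", function(object) {
  if (object@lMinMax <= 0 || object@dpNormMax <= 0)
    return("thresholds must be strictly positive")
  TRUE
})

#' Ligand ranking report
#'
#' Per-ligand predictions, reliability indices, filter pass flags and
#' within-filter ranks.
#'
#' @slot table data.frame with one row per ligand.
#' @slot sense "minimize" or "maximize".
#' @slot pStar surrogate reference point used for the deviation metric.
#' @slot bounds \linkS4class{ParamBounds} of the normalized metric.
#' @slot filters list of \linkS4class{FilterSpec} objects applied.
#' @exportClass RankingReport
setClass("RankingReport",
  representation(table = "data.frame", sense = "character",
                 pStar = "numeric", bounds = "ParamBounds",
                 filters = "list"))
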