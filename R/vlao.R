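## Virtual-ligand-assisted optimization (VLAO): gradient-driven
## minimization of the objective plus a smooth barrier confining the VL
## parameters to a realistic range, with full trajectory recording.

.asObjectiveFun <- function(objective) {
  if (is.function(objective)) return(objective)
  if (is(objective, "SyntheticSurface"))
    return(function(p) evalObjective(objective, p))
  stop("objective must be a SyntheticSurface or a function(p)")
}

#' Smooth barrier confining VL parameters to a realistic range
#'
#' A polynomial wall per component: zero on the central
#' \code{plateauFraction} of each range and growing as the fourth power
#' of the normalized excess outside it, so the barrier is zero at the
#' bounds midpoint, already positive at the bounds themselves, strictly
#' increasing beyond, and three times continuously differentiable.
#'
#' @param p VL parameters (numeric or \linkS4class{VLParams}).
#' @param bounds a \linkS4class{ParamBounds}.
#' @param stiffness wall stiffness (kcal/mol per unit^4 of normalized
#'   excess).
#' @param plateauFraction central fraction of each range with zero
#'   barrier.
#' @return list(value, gradient).
#' @export
barrier <- function(p, bounds, stiffness = 50, plateauFraction = 0.9) {
  v <- if (is(p, "VLParams")) unname(paramVector(p)) else as.numeric(p)
  lo <- unname(bounds@lower); up <- unname(bounds@upper)
  if (length(v) != length(lo)) stop("parameter/bounds dimension mismatch")
  w <- up - lo
  margin <- (1 - plateauFraction) / 2
  hi <- up - margin * w
  lw <- lo + margin * w
  excessHi <- pmax(0, (v - hi) / w)
  excessLo <- pmax(0, (lw - v) / w)
  val <- stiffness * sum(excessHi^4 + excessLo^4)
  grad <- stiffness * (4 * excessHi^3 / w - 4 * excessLo^3 / w)
  list(value = val, gradient = grad)
}

#' Optimize the virtual-ligand parameters against an objective (VLAO)
#'
#' Conjugate-gradient minimization of y + B(p) (or -y + B(p) when
#' maximizing), recording every accepted iterate together with the value
#' and gradient of the uncorrected objective y. The recorded trajectory
#' is the input for the trajectory-weighted surrogate; the surrogate
#' Hessians are taken of the uncorrected objective.
#'
#' @param objective a \linkS4class{SyntheticSurface} or function(p)
#'   returning list(value, gradient).
#' @param bounds \linkS4class{ParamBounds} for the barrier.
#' @param pInit initial parameters (default (1.6, 3.0, 2.0) Angstrom).
#' @param sense "minimize" or "maximize".
#' @param tol convergence tolerance on the gradient norm of y + B.
#' @param maxIter maximum accepted iterations.
#' @param barrierStiffness stiffness of the barrier wall.
#' @return A \linkS4class{VLAOTrajectory}.
#' @export
vlaoOptimize <- function(objective, bounds, pInit = defaultInitParams(),
                         sense = c("minimize", "maximize"), tol = 1e-6,
                         maxIter = 500L, barrierStiffness = 50) {
  sense <- match.arg(sense)
  objFun <- .asObjectiveFun(objective)
  sgn <- if (sense == "minimize") 1 else -1
  p0 <- if (is(pInit, "VLParams")) unname(paramVector(pInit))
        else as.numeric(pInit)
  rawValues <- numeric(0)
  rawGrads <- list()
  fn <- function(p) {
    ob <- objFun(p)
    br <- barrier(p, bounds, stiffness = barrierStiffness)
    list(value = sgn * ob$value + br$value,
         gradient = sgn * ob$gradient + br$gradient,
         raw = ob)
  }
  ## run CG, then re-derive the uncorrected objective along the accepted
  ## trajectory from the penalized values (exact: B and sign are known)
  res <- cgMinimize(fn, p0, tol = tol, maxIter = maxIter, positive = TRUE)
  k <- nrow(res$params)
  vals <- numeric(k); grads <- matrix(NA_real_, k, length(p0))
  for (i in seq_len(k)) {
    ob <- objFun(res$params[i, ])
    vals[i] <- ob$value
    grads[i, ] <- ob$gradient
  }
  new("VLAOTrajectory", params = res$params, values = vals,
      gradients = grads, penalized = res$values,
      pStar = res$p, fStar = vals[k],
      iterations = as.integer(res$iterations), converged = res$converged,
      sense = sense)
}

setMethod("show", "VLAOTrajectory", function(object) {
  cat(sprintf(
    paste0("VLAOTrajectory (%s): %d accepted iterations%s\n",
           "  p* = (%s), objective %.4f -> %.4f kcal/mol\n"),
    object@sense, object@iterations,
    if (object@converged) "" else " (not converged)",
    paste(sprintf("%.4f", object@pStar), collapse = ", "),
    object@values[1L], object@fStar))
})

#' Final optimized parameters of a VLAO run
#' @param traj a \linkS4class{VLAOTrajectory}.
#' @return numeric parameter vector p*.
#' @export
optimizedParams <- function(traj) traj@pStar

#' Numerical Hessian by central differences of gradients
#'
#' H[, j] = (g(p + h e_j) - g(p - h e_j)) / (2h), symmetrized as
#' (H + H') / 2. Used for the surrogate Hessians of the uncorrected
#' objective.
#'
#' @param objective objective backend (see \code{\link{vlaoOptimize}}).
#' @param p expansion point.
#' @param step finite-difference step h (> 0).
#' @return symmetric n x n matrix.
#' @export
numericalHessian <- function(objective, p, step = 1e-4) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("step must be a single positive number")
  objFun <- .asObjectiveFun(objective)
  v <- if (is(p, "VLParams")) unname(paramVector(p)) else as.numeric(p)
  n <- length(v)
  H <- matrix(NA_real_, n, n)
  for (j in seq_len(n)) {
    e <- rep(0, n); e[j] <- step
    H[, j] <- (objFun(v + e)$gradient - objFun(v - e)$gradient) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Serialize a VLAO trajectory to JSON
#'
#' Writes iterates, objective values, gradients and the final point; the
#' file is the input contract for surrogate construction.
#'
#' @param traj a \linkS4class{VLAOTrajectory}.
#' @param path output path.
#' @return path, invisibly.
#' @export
writeTrajectory <- function(traj, path) {
  jsonlite::write_json(
    list(sense = traj@sense,
         params = traj@params, values = traj@values,
         gradients = traj@gradients, penalized = traj@penalized,
         pStar = traj@pStar, fStar = traj@fStar,
         iterations = traj@iterations, converged = traj@converged),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' Read a VLAO trajectory from JSON
#'
#' @param path file written by \code{\link{writeTrajectory}}.
#' @return A \linkS4class{VLAOTrajectory}.
#' @export
readTrajectory <- function(path) {
  j <- jsonlite::fromJSON(path)
  new("VLAOTrajectory",
      params = as.matrix(j$params),
      values = as.numeric(j$values),
      gradients = as.matrix(j$gradients),
      penalized = as.numeric(j$penalized),
      pStar = as.numeric(j$pStar), fStar = as.numeric(j$fStar),
      iterations = as.integer(j$iterations),
      converged = as.logical(j$converged), sense = j$sense)
}
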