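## Surrogate models of the virtual-ligand objective: single-point
## second-order Taylor expansion with PSD-clipped Hessian, the
## inverse-square-distance weighted average of Taylor expansions along
## the VLAO trajectory, and direct backend evaluation.

#' Clip a symmetric matrix to positive semidefiniteness
#'
#' Eigendecomposes (after symmetrizing) and replaces negative eigenvalues
#' by exactly zero, keeping the eigenvectors. Because the VLAO optimum is
#' a minimum of the barrier-corrected objective rather than of the
#' objective itself, the raw Hessian can carry negative eigenvalues that
#' would make the quadratic model dive unrealistically far from the
#' reference point; clipping removes exactly those directions. The result
#' is the Frobenius-nearest PSD matrix and clipping is idempotent.
#'
#' @param H symmetric numeric matrix.
#' @return symmetric positive-semidefinite matrix of the same dimension.
#' @export
clipPSD <- function(H) {
  H <- as.matrix(H)
  if (!all(is.finite(H))) stop("Hessian entries must be finite")
  Hs <- (H + t(H)) / 2
  eg <- eigen(Hs, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  Hc <- eg$vectors %*% (vals * t(eg$vectors))
  (Hc + t(Hc)) / 2
}

#' Construct a Taylor surrogate
#'
#' Realizes the quadratic model around a reference point p*, clipping the
#' Hessian to positive semidefiniteness by default.
#'
#' @param pStar reference point.
#' @param f0 objective value at pStar.
#' @param gradient gradient at pStar.
#' @param hessian Hessian at pStar (symmetrized and clipped here).
#' @param clip logical; clip negative eigenvalues (default TRUE).
#' @return A \linkS4class{TaylorSurrogate}.
#' @export
taylorSurrogate <- function(pStar, f0, gradient, hessian, clip = TRUE) {
  pStar <- if (is(pStar, "VLParams")) unname(paramVector(pStar))
           else as.numeric(pStar)
  H <- (as.matrix(hessian) + t(as.matrix(hessian))) / 2
  if (clip) H <- clipPSD(H)
  new("TaylorSurrogate", pStar = pStar, f0 = as.numeric(f0),
      g = as.numeric(gradient), Hc = H)
}

#' Build a Taylor surrogate from a backend at a point
#'
#' Evaluates value and gradient at pStar and the Hessian by central
#' differences of gradients.
#'
#' @param objective objective backend (surface or function).
#' @param pStar expansion point.
#' @param step finite-difference step for the Hessian.
#' @param clip clip the Hessian to PSD (default TRUE).
#' @return A \linkS4class{TaylorSurrogate}.
#' @export
taylorSurrogateAt <- function(objective, pStar, step = 1e-4, clip = TRUE) {
  objFun <- .asObjectiveFun(objective)
  v <- if (is(pStar, "VLParams")) unname(paramVector(pStar))
       else as.numeric(pStar)
  ob <- objFun(v)
  H <- numericalHessian(objective, v, step = step)
  taylorSurrogate(v, ob$value, ob$gradient, H, clip = clip)
}

setMethod("show", "TaylorSurrogate", function(object) {
  ev <- eigen(object@Hc, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf(
    paste0("TaylorSurrogate: p* = (%s), f0 = %.4f kcal/mol, ",
           "Hessian eigenvalues [%s]\n"),
    paste(sprintf("%.4f", object@pStar), collapse = ", "), object@f0,
    paste(sprintf("%.3g", ev), collapse = ", ")))
})

#' Evaluate a Taylor surrogate
#'
#' f0 + g' dp + dp' Hc dp / 2 with dp = p - p*.
#'
#' @param s a \linkS4class{TaylorSurrogate}.
#' @param p query parameters.
#' @return predicted objective value (kcal/mol).
#' @export
taylorEval <- function(s, p) {
  v <- if (is(p, "VLParams")) unname(paramVector(p)) else as.numeric(p)
  if (length(v) != length(s@pStar)) stop("parameter dimension mismatch")
  dp <- v - s@pStar
  s@f0 + sum(s@g * dp) + 0.5 * sum(dp * (s@Hc %*% dp))
}

#' Build the trajectory-weighted surrogate
#'
#' One Taylor surrogate is built at every retained VLAO iterate (value
#' and gradient from the trajectory record, Hessian by central
#' differences of backend gradients, clipped like the single-point
#' surrogate). Long trajectories can be subsampled to at most
#' \code{maxMembers} points (always keeping the final one).
#'
#' @param traj a \linkS4class{VLAOTrajectory}.
#' @param objective the objective backend the trajectory was run on
#'   (needed for the member Hessians).
#' @param bounds \linkS4class{ParamBounds} defining the normalized
#'   distance metric of the weights.
#' @param epsilon weight-singularity guard in normalized units.
#' @param maxMembers optional cap on the number of members.
#' @param step Hessian finite-difference step.
#' @param clip clip member Hessians to PSD (default TRUE).
#' @return A \linkS4class{TrajectorySurrogate}.
#' @export
trajectorySurrogate <- function(traj, objective, bounds, epsilon = 1e-8,
                                maxMembers = NULL, step = 1e-4,
                                clip = TRUE) {
  k <- nrow(traj@params)
  idx <- seq_len(k)
  if (!is.null(maxMembers) && k > maxMembers)
    idx <- unique(c(round(seq(1L, k, length.out = maxMembers)), k))
  members <- lapply(idx, function(i) {
    H <- numericalHessian(objective, traj@params[i, ], step = step)
    taylorSurrogate(traj@params[i, ], traj@values[i], traj@gradients[i, ],
                    H, clip = clip)
  })
  new("TrajectorySurrogate", members = members, bounds = bounds,
      epsilon = epsilon)
}

setMethod("show", "TrajectorySurrogate", function(object) {
  cat(sprintf("TrajectorySurrogate: %d members, epsilon = %g\n",
              length(object@members), object@epsilon))
})

#' Evaluate the trajectory-weighted surrogate
#'
#' Inverse-square-distance weighted average of the member Taylor values,
#' with distances measured by the range-normalized deviation. If the
#' query point lies within epsilon of a member reference point, that
#' member's Taylor value is returned (the singular-weight limit).
#'
#' @param ts a \linkS4class{TrajectorySurrogate}.
#' @param p query parameters.
#' @return predicted objective value (kcal/mol).
#' @export
weightedEval <- function(ts, p) {
  if (length(ts@members) == 0L) stop("empty trajectory surrogate")
  v <- if (is(p, "VLParams")) unname(paramVector(p)) else as.numeric(p)
  d <- vapply(ts@members,
              function(s) deltaPNorm(v, s@pStar, ts@bounds), numeric(1))
  if (min(d) <= ts@epsilon)
    return(taylorEval(ts@members[[which.min(d)]], v))
  w <- 1 / d^2
  vals <- vapply(ts@members, taylorEval, numeric(1), p = v)
  sum(w * vals) / sum(w)
}

#' Direct objective prediction
#'
#' Evaluates the objective backend itself at the query point (no
#' surrogate error).
#'
#' @param backend objective backend (surface or function).
#' @param p query parameters.
#' @return objective value (kcal/mol).
#' @export
predictDirect <- function(backend, p) .asObjectiveFun(backend)(p)$value

#' Predict the objective with any surrogate or backend
#'
#' Generic dispatcher used by the ranking module: accepts a
#' \linkS4class{TaylorSurrogate}, a \linkS4class{TrajectorySurrogate}, a
#' \linkS4class{SyntheticSurface} (direct mode) or a plain function(p)
#' returning a value.
#'
#' @param model surrogate or backend.
#' @param p query parameters.
#' @return predicted objective value.
#' @export
predictY <- function(model, p) {
  if (is(model, "TaylorSurrogate")) return(taylorEval(model, p))
  if (is(model, "TrajectorySurrogate")) return(weightedEval(model, p))
  if (is(model, "SyntheticSurface")) return(predictDirect(model, p))
  if (is.function(model)) {
    out <- model(p)
    return(if (is.list(out)) out$value else as.numeric(out))
  }
  stop("unsupported surrogate type: ", class(model)[1L])
}
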