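## Synthetic analytic energy backend.
##
## Supplies smooth objective (F) and descriptor (G) surfaces over the VL
## parameter space with closed-form gradients, standing in for the
## quantum-chemistry engine during database building and testing.

#' Construct a synthetic analytic energy surface
#'
#' The objective is a positive-definite quadratic centered at \code{p0}
#' plus an optional Gaussian bump whose amplitude defaults to a fraction
#' \code{bumpFraction} of the quadratic range over the bounds, so that
#' Taylor-surrogate error grows smoothly with distance from the expansion
#' point. The descriptor map is affine (exact-oracle mode) plus an
#' optional mild quadratic warp. Identical seeds yield identical surfaces.
#'
#' @param n parameter dimension (default 3: r0, a1, b1).
#' @param m descriptor dimension, m > n (default 16 fragments).
#' @param seed integer seed for drawing the surface coefficients.
#' @param bounds \linkS4class{ParamBounds} the surface lives on.
#' @param bumpFraction Gaussian bump amplitude as a fraction of the
#'   quadratic objective range over the bounds (0 = pure quadratic).
#' @param warp quadratic warp amplitude of the descriptor map
#'   (0 = exactly affine).
#' @param f0 objective offset (kcal/mol).
#' @return A \linkS4class{SyntheticSurface}.
#' @examples
#' surf <- syntheticSurface(seed = 1)
#' evalObjective(surf, defaultInitParams())$value
#' @export
syntheticSurface <- function(n = 3L, m = 16L, seed = 1L,
                             bounds = defaultBounds(),
                             bumpFraction = 0.1, warp = 0, f0 = -20) {
  n <- as.integer(n); m <- as.integer(m)
  if (length(bounds@lower) != n)
    bounds <- paramBounds(rep(bounds@lower, length.out = n),
                          rep(bounds@upper, length.out = n))
  rng <- local({
    set.seed(seed)
    lo <- unname(bounds@lower); up <- unname(bounds@upper); w <- up - lo
    ## objective: PD quadratic with curvatures of a few kcal/mol/A^2
    Q <- qr.Q(qr(matrix(rnorm(n * n), n, n)))
    A <- Q %*% diag(runif(n, 2, 10), n) %*% t(Q)
    p0 <- lo + runif(n, 0.25, 0.75) * w
    ## quadratic range over the box corners
    corners <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    cp <- t(t(corners) * w + lo)
    quadRange <- max(apply(cp, 1, function(p) {
      d <- p - p0; 0.5 * sum(d * (A %*% d))
    }))
    bumpAmp <- bumpFraction * quadRange
    bumpCenter <- lo + runif(n, 0.2, 0.8) * w
    bumpWidth <- 0.35 * mean(w)
    ## descriptor map: dissociation energies of tens of kcal/mol with
    ## ligand sensitivity of a few kcal/mol per Angstrom
    g0 <- rnorm(m, 30, 10)
    B <- matrix(rnorm(m * n, 0, 3), m, n)
    C <- lapply(seq_len(m), function(j) {
      S <- matrix(rnorm(n * n, 0, 0.5), n, n); (S + t(S)) / 2
    })
    list(A = A, p0 = p0, bumpAmp = bumpAmp, bumpCenter = bumpCenter,
         bumpWidth = bumpWidth, g0 = g0, B = B, C = C)
  })
  new("SyntheticSurface", n = n, m = m, p0 = rng$p0, A = rng$A, f0 = f0,
      bumpAmp = rng$bumpAmp, bumpCenter = rng$bumpCenter,
      bumpWidth = rng$bumpWidth, g0 = rng$g0, B = rng$B,
      warp = warp, warpMats = rng$C, bounds = bounds, seed = as.integer(seed))
}

setMethod("show", "SyntheticSurface", function(object) {
  cat(sprintf(paste0("SyntheticSurface: n = %d, m = %d, seed = %d, ",
                     "bump amplitude = %.3g kcal/mol, warp = %g\n"),
              object@n, object@m, object@seed, object@bumpAmp,
              object@warp))
})

.pvec <- function(p, n) {
  v <- if (is(p, "VLParams")) unname(paramVector(p)) else as.numeric(p)
  if (length(v) != n) stop("parameter dimension mismatch: expected ", n)
  if (!all(is.finite(v))) stop("parameters must be finite")
  v
}

#' Evaluate the synthetic objective
#'
#' @param surface a \linkS4class{SyntheticSurface}.
#' @param p VL parameters (\linkS4class{VLParams} or numeric vector).
#' @return list(value, gradient): objective value (kcal/mol) and its
#'   analytic gradient with respect to p.
#' @export
evalObjective <- function(surface, p) {
  v <- .pvec(p, surface@n)
  d <- v - surface@p0
  val <- surface@f0 + 0.5 * sum(d * (surface@A %*% d))
  grad <- as.vector(surface@A %*% d)
  if (surface@bumpAmp != 0) {
    db <- v - surface@bumpCenter
    s2 <- surface@bumpWidth^2
    e <- surface@bumpAmp * exp(-sum(db * db) / (2 * s2))
    val <- val + e
    grad <- grad - e * db / s2
  }
  list(value = val, gradient = grad)
}

#' Evaluate the synthetic descriptor map
#'
#' Returns the m-dimensional descriptor-generating energies G(p) and the
#' exact m x n Jacobian.
#'
#' @param surface a \linkS4class{SyntheticSurface}.
#' @param p VL parameters.
#' @return list(value, jacobian).
#' @export
evalDescriptors <- function(surface, p) {
  v <- .pvec(p, surface@n)
  val <- surface@g0 + as.vector(surface@B %*% v)
  jac <- surface@B
  if (surface@warp != 0) {
    quad <- vapply(surface@warpMats, function(Cj) sum(v * (Cj %*% v)), numeric(1))
    val <- val + surface@warp * quad
    jac <- jac + surface@warp *
      2 * t(vapply(surface@warpMats, function(Cj) as.vector(Cj %*% v),
                   numeric(surface@n)))
  }
  list(value = val, jacobian = jac)
}

#' Generate a synthetic "real" ligand
#'
#' Places a descriptor vector at G(pTrue) plus an offset of magnitude
#' \code{delta} along a direction orthogonal to the local tangent space of
#' the descriptor surface, emulating the component of a real ligand that
#' the virtual ligand cannot represent. The true parameters and offset are
#' recorded as ground truth.
#'
#' @param surface a \linkS4class{SyntheticSurface}.
#' @param pTrue true VL parameters of the ligand.
#' @param delta orthogonal offset magnitude (>= 0, energy units).
#' @param seed seed for the direction draw.
#' @return list(x, pTrue, delta, direction).
#' @export
makeSyntheticLigand <- function(surface, pTrue, delta, seed = 1L) {
  if (delta < 0) stop("delta must be nonnegative")
  v <- .pvec(pTrue, surface@n)
  gd <- evalDescriptors(surface, v)
  u <- rep(0, surface@m)
  if (delta > 0) {
    Qfull <- qr.Q(qr(gd$jacobian), complete = TRUE)
    nullBasis <- Qfull[, (surface@n + 1L):surface@m, drop = FALSE]
    set.seed(seed)
    z <- rnorm(ncol(nullBasis))
    u <- as.vector(nullBasis %*% z)
    u <- u / sqrt(sum(u * u))
  }
  list(x = gd$value + delta * u, pTrue = v, delta = delta, direction = u)
}

#' Generate a synthetic ligand set
#'
#' Draws \code{k} ligands with true parameters uniform over the surface
#' bounds and orthogonal offsets uniform in \code{deltaRange}, emulating
#' the spread of projection residuals seen across real monodentate
#' phosphines (roughly 1-4 kcal/mol-scale units).
#'
#' @param surface a \linkS4class{SyntheticSurface}.
#' @param k number of ligands (default 21).
#' @param deltaRange range of orthogonal offset magnitudes.
#' @param seed integer seed.
#' @return list of ligands as returned by \code{\link{makeSyntheticLigand}},
#'   named L1..Lk.
#' @export
syntheticLigandSet <- function(surface, k = 21L, deltaRange = c(0.5, 3),
                               seed = 1L) {
  set.seed(seed)
  lo <- surface@bounds@lower; w <- surface@bounds@upper - lo
  ps <- t(replicate(k, lo + runif(surface@n) * w))
  deltas <- runif(k, deltaRange[1L], deltaRange[2L])
  seeds <- sample.int(.Machine$integer.max %/% 2L, k)
  ligs <- lapply(seq_len(k), function(i)
    makeSyntheticLigand(surface, ps[i, ], deltas[i], seed = seeds[i]))
  names(ligs) <- paste0("L", seq_len(k))
  ligs
}
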