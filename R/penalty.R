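## Penalty-function energies of the virtual ligand.
##
## The VL replaces the substituents of PR3 by three Cl* atoms subject to
## (i) a harmonic keep potential on each P-Cl* distance, (ii) a harmonic
## keep-angle potential on each Cl*-P-Cl* angle, and (iii) an ovoid-based
## Lennard-Jones potential between each P-Cl* axis and the environment
## atoms. All gradients are analytic; units kcal/mol, Angstrom, degrees.

RAD2DEG <- 180 / pi

skewMat <- function(v)
  matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
## skewMat(v) %*% x == v x x (cross product)

#' Harmonic keep-potential energy
#'
#' E = sum over the three P-Cl* bonds of kKeep * (r - r0)^2, encoding the
#' electronic character of the virtual ligand through the equilibrium
#' distance r0.
#'
#' @param geom a \linkS4class{MolecularGeometry}.
#' @param r0 equilibrium P-Cl* distance (Angstrom).
#' @param kKeep force constant (kcal/mol/Angstrom^2).
#' @return list(energy, gradient) with gradient an natoms x 3 matrix of
#'   exact derivatives with respect to the Cartesian coordinates.
#' @export
keepEnergy <- function(geom, r0, kKeep = 100) {
  if (length(geom@clIndices) != 3L) stop("three Cl* indices required")
  xP <- geom@coords[geom@pIndex, ]
  E <- 0
  grad <- matrix(0, nrow(geom@coords), 3)
  dEdr0 <- 0
  for (ci in geom@clIndices) {
    r <- geom@coords[ci, ] - xP
    n <- sqrt(sum(r * r))
    if (n < 1e-12) stop("Cl* coincident with P")
    u <- r / n
    E <- E + kKeep * (n - r0)^2
    g <- 2 * kKeep * (n - r0) * u
    grad[ci, ] <- grad[ci, ] + g
    grad[geom@pIndex, ] <- grad[geom@pIndex, ] - g
    dEdr0 <- dEdr0 - 2 * kKeep * (n - r0)
  }
  list(energy = E, gradient = grad, dEdr0 = dEdr0)
}

#' Harmonic keep-angle-potential energy
#'
#' E = sum over the three Cl*-P-Cl* angles of kAngle * (phi - phi0)^2,
#' with phi in degrees.
#'
#' @param geom a \linkS4class{MolecularGeometry}.
#' @param phi0 equilibrium angle (degrees).
#' @param kAngle force constant (kcal/mol/degree^2).
#' @return list(energy, gradient) as in \code{\link{keepEnergy}}.
#' @export
keepAngleEnergy <- function(geom, phi0 = 65, kAngle = 0.1) {
  cl <- geom@clIndices
  if (length(cl) != 3L) stop("three Cl* indices required")
  xP <- geom@coords[geom@pIndex, ]
  E <- 0
  grad <- matrix(0, nrow(geom@coords), 3)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  for (pr in pairs) {
    i <- cl[pr[1L]]; j <- cl[pr[2L]]
    ri <- geom@coords[i, ] - xP; rj <- geom@coords[j, ] - xP
    ni <- sqrt(sum(ri * ri)); nj <- sqrt(sum(rj * rj))
    ui <- ri / ni; uj <- rj / nj
    cphi <- sum(ui * uj)
    if (abs(cphi) > 1 - 1e-10)
      stop("degenerate configuration: collinear Cl*-P-Cl* angle")
    phi <- acos(cphi)
    dphi <- phi * RAD2DEG - phi0
    E <- E + kAngle * dphi^2
    ## d(phi)/dx via d(cos phi); chain to degrees
    pref <- 2 * kAngle * dphi * RAD2DEG * (-1 / sqrt(1 - cphi^2))
    dci <- (uj - cphi * ui) / ni   # d(cos phi)/d xi
    dcj <- (ui - cphi * uj) / nj
    grad[i, ] <- grad[i, ] + pref * dci
    grad[j, ] <- grad[j, ] + pref * dcj
    grad[geom@pIndex, ] <- grad[geom@pIndex, ] - pref * (dci + dcj)
  }
  list(energy = E, gradient = grad)
}

## Frame of one ovoid axis and the Jacobians of its basis vectors with
## respect to the positions of the frame atoms (P and the three Cl*).
## The thickness direction is the lone-pair axis component orthogonal to
## the P-Cl* axis; the width direction completes the right-handed frame.
ovoidFrames <- function(geom) {
  xP <- geom@coords[geom@pIndex, ]
  cl <- geom@clIndices
  I3 <- diag(3)
  u <- vector("list", 3L); n <- numeric(3L); Pu <- vector("list", 3L)
  for (k in 1:3) {
    r <- geom@coords[cl[k], ] - xP
    n[k] <- sqrt(sum(r * r))
    if (n[k] < 1e-12) stop("Cl* coincident with P")
    u[[k]] <- r / n[k]
    Pu[[k]] <- I3 - tcrossprod(u[[k]])
  }
  w0 <- -(u[[1L]] + u[[2L]] + u[[3L]])
  nw <- sqrt(sum(w0 * w0))
  if (nw < 1e-8) stop("degenerate frame: planar PCl*3, lone-pair axis undefined")
  w <- w0 / nw
  Pw <- I3 - tcrossprod(w)
  ## Jacobians of w wrt each frame atom ("P", "Cl1".."Cl3")
  Jw <- list(P = matrix(0, 3, 3), Cl1 = NULL, Cl2 = NULL, Cl3 = NULL)
  for (k in 1:3) {
    Jw[[paste0("Cl", k)]] <- (Pw / nw) %*% (-Pu[[k]] / n[k])
    Jw$P <- Jw$P + (Pw / nw) %*% (Pu[[k]] / n[k])
  }
  list(xP = xP, cl = cl, u = u, n = n, Pu = Pu, w = w, Jw = Jw, I3 = I3)
}

#' Ovoid-based Lennard-Jones steric energy
#'
#' One ovoid is attached to each P-Cl* axis: a superellipsoid-like closed
#' surface centered at distance d from P along the axis, with half-axes
#' (a1, a2) across (width), (b1, b2) through (thickness) and lengths
#' (c1, c2) along the axis. For an environment atom at local coordinates
#' (t, xa, xb) the scaled radius
#' q = sqrt((t/c)^2 + (xa/a)^2 + (xb/b)^2) equals 1 on the ovoid surface,
#' and a 12-6 Lennard-Jones term epsLJ * (q^-12 - 2 q^-6) is accumulated.
#' The energy vanishes as environment atoms recede and is singular if an
#' atom coincides with an ovoid center. Gradients with respect to all
#' Cartesian coordinates (including the frame atoms) and with respect to
#' (a1, b1) are exact for this functional form, which is isolated here so
#' it can be swapped for an alternative ovoid definition.
#'
#' @param geom a \linkS4class{MolecularGeometry}.
#' @param params a \linkS4class{VLParams}.
#' @param settings a \linkS4class{FixedVLSettings}.
#' @return list(energy, gradient, gradParams) where gradient is natoms x 3
#'   and gradParams is c(a1 = ..., b1 = ...).
#' @export
ovoidLJEnergy <- function(geom, params, settings = fixedVLSettings()) {
  if (length(geom@envIndices) == 0L)
    return(list(energy = 0,
                gradient = matrix(0, nrow(geom@coords), 3),
                gradParams = c(a1 = 0, b1 = 0)))
  ax <- ovoidHalfAxes(params, settings)
  eps <- settings@epsLJ
  fr <- ovoidFrames(geom)
  frameAtoms <- c(P = geom@pIndex,
                  Cl1 = fr$cl[1L], Cl2 = fr$cl[2L], Cl3 = fr$cl[3L])
  E <- 0
  grad <- matrix(0, nrow(geom@coords), 3)
  gA1 <- 0; gB1 <- 0
  for (k in 1:3) {
    u <- fr$u[[k]]
    ## Jacobian of this axis direction wrt frame atoms
    Ju <- list(P = -fr$Pu[[k]] / fr$n[k], Cl1 = matrix(0, 3, 3),
               Cl2 = matrix(0, 3, 3), Cl3 = matrix(0, 3, 3))
    Ju[[paste0("Cl", k)]] <- fr$Pu[[k]] / fr$n[k]
    ## thickness direction: lone-pair axis orthogonalized against u
    s <- sum(fr$w * u)
    b0 <- fr$w - s * u
    nb <- sqrt(sum(b0 * b0))
    if (nb < 1e-8) stop("degenerate frame: axis parallel to lone-pair axis")
    bh <- b0 / nb
    Pb <- fr$I3 - tcrossprod(bh)
    ah <- c(u[2] * bh[3] - u[3] * bh[2],
            u[3] * bh[1] - u[1] * bh[3],
            u[1] * bh[2] - u[2] * bh[1])
    Jbh <- list(); Jah <- list(); Jc <- list()
    for (X in names(frameAtoms)) {
      Jb0 <- fr$Jw[[X]] -
        outer(u, as.vector(crossprod(u, fr$Jw[[X]]) +
                           crossprod(fr$w, Ju[[X]]))) -
        s * Ju[[X]]
      Jbh[[X]] <- (Pb / nb) %*% Jb0
      Jah[[X]] <- -skewMat(bh) %*% Ju[[X]] + skewMat(u) %*% Jbh[[X]]
      Jc[[X]] <- settings@d * Ju[[X]] +
        (if (X == "P") fr$I3 else matrix(0, 3, 3))
    }
    center <- fr$xP + settings@d * u
    for (e in geom@envIndices) {
      rel <- geom@coords[e, ] - center
      tt <- sum(rel * u); xa <- sum(rel * ah); xb <- sum(rel * bh)
      L <- if (tt >= 0) settings@c1 else settings@c2
      sa <- if (xa >= 0) ax[["a1"]] else ax[["a2"]]
      sb <- if (xb >= 0) ax[["b1"]] else ax[["b2"]]
      q2 <- (tt / L)^2 + (xa / sa)^2 + (xb / sb)^2
      if (q2 < 1e-16)
        stop("environment atom ", e, " coincident with ovoid center ",
             "(singular distance)")
      q6 <- q2^3
      E <- E + eps * (1 / q6^2 - 2 / q6)
      dEdq2 <- -6 * eps * (1 / (q6^2 * q2) - 1 / (q6 * q2))
      ## environment atom: frame fixed, d rel = I
      dq2env <- 2 * (tt / L^2) * u + 2 * (xa / sa^2) * ah +
        2 * (xb / sb^2) * bh
      grad[e, ] <- grad[e, ] + dEdq2 * dq2env
      ## frame atoms: chain rule through u, ah, bh, center
      for (X in names(frameAtoms)) {
        Drel <- -Jc[[X]]
        Dt <- as.vector(crossprod(u, Drel) + crossprod(rel, Ju[[X]]))
        Dxa <- as.vector(crossprod(ah, Drel) + crossprod(rel, Jah[[X]]))
        Dxb <- as.vector(crossprod(bh, Drel) + crossprod(rel, Jbh[[X]]))
        dq2 <- 2 * (tt / L^2) * Dt + 2 * (xa / sa^2) * Dxa +
          2 * (xb / sb^2) * Dxb
        ai <- frameAtoms[[X]]
        grad[ai, ] <- grad[ai, ] + dEdq2 * dq2
      }
      ## half-axis parameter gradients (symmetric mode ties a2 = a1)
      if (settings@symmetric || xa >= 0)
        gA1 <- gA1 + dEdq2 * (-2 * xa^2 / sa^3)
      if (settings@symmetric || xb >= 0)
        gB1 <- gB1 + dEdq2 * (-2 * xb^2 / sb^3)
    }
  }
  list(energy = E, gradient = grad, gradParams = c(a1 = gA1, b1 = gB1))
}

#' Total virtual-ligand penalty energy
#'
#' Sum of the keep, keep-angle and ovoid Lennard-Jones terms, with
#' additive gradients.
#'
#' @param geom a \linkS4class{MolecularGeometry}.
#' @param params a \linkS4class{VLParams}.
#' @param settings a \linkS4class{FixedVLSettings}.
#' @return list(energy, gradient, gradParams, terms) where gradParams is
#'   c(r0, a1, b1) and terms holds the three component energies.
#' @export
vlPenaltyEnergy <- function(geom, params, settings = fixedVLSettings()) {
  kp <- keepEnergy(geom, params@r0, settings@kKeep)
  ka <- keepAngleEnergy(geom, settings@phi0, settings@kAngle)
  ov <- ovoidLJEnergy(geom, params, settings)
  list(energy = kp$energy + ka$energy + ov$energy,
       gradient = kp$gradient + ka$gradient + ov$gradient,
       gradParams = c(r0 = kp$dEdr0, ov$gradParams),
       terms = c(keep = kp$energy, keepAngle = ka$energy,
                 ovoidLJ = ov$energy))
}
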