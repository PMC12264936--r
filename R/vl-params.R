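#' Construct a virtual-ligand parameter vector
#'
#' @param r0 equilibrium P-Cl distance (Angstrom), or a numeric vector of
#'   length 3 giving (r0, a1, b1).
#' @param a1 ovoid width half-axis (Angstrom).
#' @param b1 ovoid thickness half-axis (Angstrom).
#' @return A \linkS4class{VLParams} object.
#' @examples
#' vlParams(1.557, 2.132, 0.608)  # PMe3-like parameters
#' @export
vlParams <- function(r0, a1, b1) {
  if (missing(a1) && length(r0) == 3L) {
    v <- as.numeric(r0)
    return(new("VLParams", r0 = v[1L], a1 = v[2L], b1 = v[3L]))
  }
  new("VLParams", r0 = as.numeric(r0), a1 = as.numeric(a1),
      b1 = as.numeric(b1))
}

#' Extract the plain parameter vector
#'
#' @param x a \linkS4class{VLParams} object or numeric vector.
#' @return Named numeric vector c(r0, a1, b1).
#' @export
paramVector <- function(x) {
  if (is(x, "VLParams")) return(c(r0 = x@r0, a1 = x@a1, b1 = x@b1))
  v <- as.numeric(x)
  if (length(v) == 3L && is.null(names(x))) names(v) <- c("r0", "a1", "b1")
  else names(v) <- names(x)
  v
}

setMethod("show", "VLParams", function(object) {
  cat(sprintf("VLParams: r0 = %.3f A, a1 = %.3f A, b1 = %.3f A\n",
              object@r0, object@a1, object@b1))
})

#' Fixed virtual-ligand settings
#'
#' Defaults follow the standard virtual-ligand setup: phi0 = 65 degrees,
#' c1 = c2 = d = 3.0 Angstrom, symmetric substituent mode (a2 = a1,
#' b2 = b1). Force constants default to kKeep = 100 kcal/mol/A^2 and
#' kAngle = 0.1 kcal/mol/deg^2; the ovoid Lennard-Jones well depth
#' defaults to 0.1 kcal/mol.
#'
#' @param phi0 equilibrium Cl-P-Cl angle (degrees).
#' @param c1,c2 ovoid lengths along the P-Cl axis (Angstrom).
#' @param d ovoid center offset from P (Angstrom).
#' @param kKeep,kAngle harmonic force constants.
#' @param epsLJ Lennard-Jones well depth (kcal/mol).
#' @param a2,b2 mirror half-axes; NA ties them to a1, b1 (symmetric mode).
#' @return A \linkS4class{FixedVLSettings} object.
#' @export
fixedVLSettings <- function(phi0 = 65, c1 = 3.0, c2 = 3.0, d = 3.0,
                            kKeep = 100, kAngle = 0.1, epsLJ = 0.1,
                            a2 = NA_real_, b2 = NA_real_) {
  new("FixedVLSettings", phi0 = phi0, a2 = a2, b2 = b2, c1 = c1, c2 = c2,
      d = d, kKeep = kKeep, kAngle = kAngle, epsLJ = epsLJ,
      symmetric = is.na(a2) && is.na(b2))
}

setMethod("show", "FixedVLSettings", function(object) {
  cat(sprintf(paste0("FixedVLSettings: phi0 = %g deg, c1 = c2 = %g A, ",
                     "d = %g A, kKeep = %g, kAngle = %g, epsLJ = %g, %s\n"),
              object@phi0, object@c1, object@d, object@kKeep, object@kAngle,
              object@epsLJ,
              if (object@symmetric) "symmetric (a2 = a1, b2 = b1)"
              else sprintf("a2 = %g, b2 = %g", object@a2, object@b2)))
})

#' Construct parameter bounds
#'
#' @param lower,upper numeric vectors of equal length (componentwise
#'   lower < upper).
#' @return A \linkS4class{ParamBounds} object.
#' @export
paramBounds <- function(lower, upper) {
  lo <- as.numeric(lower); up <- as.numeric(upper)
  nm <- names(lower)
  if (is.null(nm) && length(lo) == 3L) nm <- c("r0", "a1", "b1")
  names(lo) <- nm; names(up) <- nm
  new("ParamBounds", lower = lo, upper = up)
}

#' Standard accessible parameter ranges
#'
#' The realistic ranges used for the barrier function and the normalized
#' deviation metric: r0 in 1.3-1.9 A, a1 in 2.0-3.5 A, b1 in 1.5-3.0 A.
#'
#' @return A \linkS4class{ParamBounds} object.
#' @export
defaultBounds <- function() {
  paramBounds(c(r0 = 1.3, a1 = 2.0, b1 = 1.5),
              c(r0 = 1.9, a1 = 3.5, b1 = 3.0))
}

#' Expanded accessible parameter ranges
#'
#' Wider ranges (r0 1.0-2.2 A, a1 1.5-5.5 A, b1 0.5-2.5 A) chosen to
#' encompass the full spread of the packaged ligand database; used to
#' study the effect of the barrier range on prediction accuracy.
#'
#' @return A \linkS4class{ParamBounds} object.
#' @export
expandedBounds <- function() {
  paramBounds(c(r0 = 1.0, a1 = 1.5, b1 = 0.5),
              c(r0 = 2.2, a1 = 5.5, b1 = 2.5))
}

#' Default VLAO / projection starting point
#'
#' The standard initial parameter set p = (1.6, 3.0, 2.0) Angstrom.
#'
#' @return Named numeric vector.
#' @export
defaultInitParams <- function() c(r0 = 1.6, a1 = 3.0, b1 = 2.0)

setMethod("show", "ParamBounds", function(object) {
  nm <- names(object@lower)
  if (is.null(nm)) nm <- paste0("p", seq_along(object@lower))
  cat("ParamBounds:\n")
  for (i in seq_along(object@lower))
    cat(sprintf("  %-3s [%g, %g]\n", nm[i], object@lower[i], object@upper[i]))
})

boundsWidth <- function(bounds) bounds@upper - bounds@lower

#' Effective mirror half-axes of the ovoid
#'
#' @param params a \linkS4class{VLParams} object.
#' @param settings a \linkS4class{FixedVLSettings} object.
#' @return Named vector c(a1, a2, b1, b2): a2 = a1 and b2 = b1 in
#'   symmetric mode.
#' @export
ovoidHalfAxes <- function(params, settings) {
  if (settings@symmetric)
    c(a1 = params@a1, a2 = params@a1, b1 = params@b1, b2 = params@b1)
  else
    c(a1 = params@a1, a2 = settings@a2, b1 = params@b1, b2 = settings@b2)
}
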