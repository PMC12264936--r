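## Projection H: map a descriptor vector x to the nearest point on the
## virtual-ligand descriptor surface G(P), returning the VL parameters
## and the residual distance l_min.

.asDescriptorFun <- function(backend) {
  if (is.function(backend)) return(backend)
  if (is(backend, "SyntheticSurface"))
    return(function(p) evalDescriptors(backend, p))
  stop("backend must be a SyntheticSurface or a function(p)")
}

#' Distance between a descriptor vector and the virtual-ligand surface
#'
#' Euclidean distance l(x, p) = ||x - G(p)|| together with the analytic
#' gradient of l^2 with respect to p (chain rule through the backend
#' Jacobian).
#'
#' @param x descriptor vector (length m).
#' @param p VL parameters.
#' @param backend descriptor backend (\linkS4class{SyntheticSurface} or
#'   function(p) returning list(value, jacobian)).
#' @return list(distance, lsq, gradLsq).
#' @export
descriptorDistance <- function(x, p, backend) {
  fn <- .asDescriptorFun(backend)
  gd <- fn(if (is(p, "VLParams")) unname(paramVector(p)) else as.numeric(p))
  x <- as.numeric(x)
  if (length(x) != length(gd$value))
    stop("descriptor dimension mismatch: x has length ", length(x),
         ", backend returns ", length(gd$value))
  r <- x - gd$value
  lsq <- sum(r * r)
  list(distance = sqrt(lsq), lsq = lsq,
       gradLsq = as.vector(-2 * crossprod(gd$jacobian, r)))
}

#' Project a descriptor vector onto the virtual-ligand surface
#'
#' Minimizes the squared distance l(x, p)^2 by conjugate gradients (the
#' square avoids the non-differentiable point at l = 0), starting from
#' p = (1.6, 3.0, 2.0) Angstrom by default. On warped (non-affine)
#' surfaces a seeded multi-start explores around the initial point and
#' the best local minimum is kept; ties are broken by smaller distance to
#' the initial point, then lexicographically.
#'
#' @param x descriptor vector.
#' @param backend descriptor backend (see
#'   \code{\link{descriptorDistance}}).
#' @param pInit initial parameters.
#' @param tol convergence tolerance on the gradient norm of l^2.
#' @param maxIter maximum CG iterations.
#' @param restarts number of additional seeded starting points.
#' @param seed seed for the restart draws.
#' @return A \linkS4class{ProjectionResult}.
#' @export
project <- function(x, backend, pInit = defaultInitParams(), tol = 1e-8,
                    maxIter = 500L, restarts = 5L, seed = 1L) {
  fn <- .asDescriptorFun(backend)
  x <- as.numeric(x)
  p0 <- if (is(pInit, "VLParams")) unname(paramVector(pInit))
        else as.numeric(pInit)
  objective <- function(p) {
    gd <- fn(p)
    r <- x - gd$value
    list(value = sum(r * r),
         gradient = as.vector(-2 * crossprod(gd$jacobian, r)))
  }
  starts <- list(p0)
  if (restarts > 0L) {
    set.seed(seed)
    for (i in seq_len(restarts))
      starts[[i + 1L]] <- p0 * exp(stats::rnorm(length(p0), 0, 0.15))
  }
  best <- NULL
  for (st in starts) {
    res <- cgMinimize(objective, st, tol = tol, maxIter = maxIter,
                      positive = TRUE)
    better <- is.null(best) ||
      res$value < best$value - 1e-12 ||
      (abs(res$value - best$value) <= 1e-12 &&
       (sum((res$p - p0)^2) < sum((best$p - p0)^2) - 1e-12 ||
        (abs(sum((res$p - p0)^2) - sum((best$p - p0)^2)) <= 1e-12 &&
         isTRUE(all(res$p <= best$p)))))
    if (better) best <- res
  }
  trace <- cbind(best$params, lsq = best$values)
  new("ProjectionResult", p = best$p, lMin = sqrt(max(best$value, 0)),
      iterations = as.integer(best$iterations),
      converged = best$converged, trace = trace)
}

setMethod("show", "ProjectionResult", function(object) {
  cat(sprintf(
    "ProjectionResult: p = (%s), l_min = %.4g, %d iterations%s\n",
    paste(sprintf("%.4f", object@p), collapse = ", "), object@lMin,
    object@iterations,
    if (object@converged) "" else " (not converged)"))
})

#' Accessors for projection results
#' @param object a \linkS4class{ProjectionResult}.
#' @return \code{projectedParams}: the parameter vector;
#'   \code{residual}: the l_min distance.
#' @export
projectedParams <- function(object) object@p

#' @rdname projectedParams
#' @export
residual <- function(object) object@lMin

#' Project a batch of descriptor vectors
#'
#' Order-preserving batch projection; per-ligand failures are collected
#' and reported with their identifiers rather than aborting the batch.
#'
#' @param xs list (optionally named) of descriptor vectors.
#' @param backend descriptor backend.
#' @param ... options passed to \code{\link{project}}.
#' @return named list of \linkS4class{ProjectionResult} objects.
#' @export
projectAll <- function(xs, backend, ...) {
  if (length(xs) == 0L) stop("empty descriptor list")
  ids <- names(xs)
  if (is.null(ids)) ids <- paste0("L", seq_along(xs))
  out <- vector("list", length(xs))
  names(out) <- ids
  errs <- character(0)
  for (i in seq_along(xs)) {
    out[[i]] <- tryCatch(project(xs[[i]], backend, ...),
                         error = function(e) {
                           errs[[length(errs) + 1L]] <<-
                             paste0(ids[i], ": ", conditionMessage(e))
                           NULL
                         })
  }
  if (length(errs))
    stop("projection failed for ", length(errs), " ligand(s): ",
         paste(errs, collapse = "; "))
  out
}

#' Build a parameter database by projecting synthetic ligands
#'
#' Convenience wrapper: projects every ligand descriptor and assembles
#' the canonical database data.frame (id, name, r0, a1, b1, l_min).
#'
#' @param ligands list of ligands with \code{$x} descriptor vectors
#'   (e.g. from \code{\link{syntheticLigandSet}}).
#' @param backend descriptor backend.
#' @param ... options passed to \code{\link{project}}.
#' @return data.frame in the parameter-database layout.
#' @export
buildParamDb <- function(ligands, backend, ...) {
  xs <- lapply(ligands, `[[`, "x")
  prs <- projectAll(xs, backend, ...)
  ids <- names(prs)
  data.frame(id = ids, name = ids,
             r0 = vapply(prs, function(r) r@p[1L], numeric(1)),
             a1 = vapply(prs, function(r) r@p[2L], numeric(1)),
             b1 = vapply(prs, function(r) r@p[3L], numeric(1)),
             l_min = vapply(prs, residual, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
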