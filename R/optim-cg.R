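## Shared conjugate-gradient engine (Polak-Ribiere with restart on
## non-descent directions, backtracking Armijo line search). Used by both
## the descriptor projection and the VLAO optimization so the two share
## identical line-search behaviour.

#' Conjugate-gradient minimization with trajectory recording
#'
#' Minimizes a smooth function given by a value/gradient callback using
#' Polak-Ribiere(+) conjugate gradients with an Armijo backtracking line
#' search (c = 1e-4, shrink 0.5). Steps into nonpositive parameter
#' components can be rejected (positivity guard for physical lengths).
#' All accepted iterates are recorded; by construction the objective is
#' non-increasing over accepted steps.
#'
#' @param fn function(p) returning list(value, gradient).
#' @param pInit numeric starting point.
#' @param tol convergence tolerance on the gradient norm.
#' @param maxIter maximum accepted iterations.
#' @param positive logical; reject steps with any component <= 0.
#' @return list(p, value, gradient, iterations, converged, params,
#'   values, gradients) where params/values/gradients record the accepted
#'   iterates (including the starting point).
#' @export
cgMinimize <- function(fn, pInit, tol = 1e-8, maxIter = 500L,
                       positive = TRUE) {
  p <- as.numeric(pInit)
  ev <- fn(p)
  f <- ev$value; g <- as.numeric(ev$gradient)
  n <- length(p)
  params <- matrix(NA_real_, maxIter + 1L, n)
  values <- numeric(maxIter + 1L)
  grads <- matrix(NA_real_, maxIter + 1L, n)
  params[1L, ] <- p; values[1L] <- f; grads[1L, ] <- g
  k <- 0L
  converged <- sqrt(sum(g * g)) <= tol
  d <- -g
  c1 <- 1e-4
  slopePrev <- NA_real_
  alphaPrev <- NA_real_
  while (!converged && k < maxIter) {
    if (sum(d * g) >= 0) d <- -g   # restart on non-descent
    slope <- sum(d * g)
    if (slope >= 0) break          # gradient numerically zero
    ## first-order initial step: carry the previous step's decrease rate
    alpha <- if (is.na(alphaPrev)) min(1, 1 / sqrt(sum(d * d)))
             else min(1e3, 2 * alphaPrev * slopePrev / slope)
    if (!is.finite(alpha) || alpha <= 0) alpha <- 1
    accepted <- FALSE
    for (bt in 1:60) {
      pTry <- p + alpha * d
      if (!positive || all(pTry > 0)) {
        evTry <- fn(pTry)
        if (is.finite(evTry$value) &&
            evTry$value <= f + c1 * alpha * slope) {
          accepted <- TRUE
          break
        }
      }
      alpha <- alpha * 0.5
    }
    if (!accepted) break
    alphaPrev <- alpha
    slopePrev <- slope
    gPrev <- g
    p <- pTry; f <- evTry$value; g <- as.numeric(evTry$gradient)
    beta <- max(0, sum(g * (g - gPrev)) / sum(gPrev * gPrev))
    d <- -g + beta * d
    k <- k + 1L
    params[k + 1L, ] <- p; values[k + 1L] <- f; grads[k + 1L, ] <- g
    converged <- sqrt(sum(g * g)) <= tol
  }
  keep <- seq_len(k + 1L)
  list(p = p, value = f, gradient = g, iterations = k,
       converged = converged,
       params = params[keep, , drop = FALSE], values = values[keep],
       gradients = grads[keep, , drop = FALSE])
}
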