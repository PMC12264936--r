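## Shared fixtures: randomized but seeded PCl*3 geometries and
## finite-difference utilities used across the gradient checks.

## A pyramidal PCl*3 core (bond lengths ~1.5-1.8 A, realistic pairwise
## angles) with a few environment atoms a couple of Angstrom away.
randomVLGeometry <- function(seed, nEnv = 4L) {
  set.seed(seed)
  xP <- rnorm(3, 0, 0.2)
  ## Cl* directions: downward-pointing cone with jitter
  cls <- t(vapply(1:3, function(i) {
    az <- 2 * pi * (i - 1) / 3 + rnorm(1, 0, 0.15)
    pol <- 2.0 + rnorm(1, 0, 0.1)   # ~115 deg from +z
    len <- 1.65 + rnorm(1, 0, 0.08)
    xP + len * c(sin(pol) * cos(az), sin(pol) * sin(az), cos(pol))
  }, numeric(3)))
  env <- t(vapply(seq_len(nEnv), function(i)
    xP + c(0, 0, 2.5) + rnorm(3, 0, 1.2), numeric(3)))
  molecularGeometry(c("P", "Cl", "Cl", "Cl", rep("C", nEnv)),
                    rbind(xP, cls, env),
                    pIndex = 1L, clIndices = 2:4,
                    envIndices = 4L + seq_len(nEnv))
}

## max relative error between an analytic coordinate gradient and the
## central finite difference of the energy
fdGradError <- function(energyFn, geom, grad, h = 1e-5) {
  mx <- 0
  for (i in seq_len(nrow(geom@coords))) {
    for (j in 1:3) {
      gp <- geom; gp@coords[i, j] <- gp@coords[i, j] + h
      gm <- geom; gm@coords[i, j] <- gm@coords[i, j] - h
      fd <- (energyFn(gp) - energyFn(gm)) / (2 * h)
      mx <- max(mx, abs(fd - grad[i, j]) / max(1, abs(fd)))
    }
  }
  mx
}

## central finite-difference gradient of a scalar function of a vector
fdGradVec <- function(fn, p, h = 1e-6) {
  vapply(seq_along(p), function(i) {
    e <- rep(0, length(p)); e[i] <- h
    (fn(p + e) - fn(p - e)) / (2 * h)
  }, numeric(1))
}
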