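test_that("PSD clipping zeroes negative eigenvalues, keeps eigenvectors,
           and is idempotent", {
  ## already-PSD input is returned unchanged
  P <- crossprod(matrix(c(2, 0.3, -0.1, 1.5, 0.2, 0.8, 0.1, -0.4, 1.1),
                        3, 3))
  expect_lt(max(abs(clipPSD(P) - (P + t(P)) / 2)), 1e-12)

  expect_equal(clipPSD(diag(c(2, -3))), diag(c(2, 0)), tolerance = 1e-12)

  set.seed(33)
  S <- matrix(rnorm(16), 4, 4); S <- (S + t(S)) / 2
  Sc <- clipPSD(S)
  ev <- eigen(Sc, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-12)
  ## idempotence
  expect_lt(max(abs(clipPSD(Sc) - Sc)), 1e-12)
  ## Sc and S commute (shared eigenvectors)
  expect_lt(max(abs(Sc %*% S - S %*% Sc)), 1e-10)
  ## Frobenius distance equals the norm of the clipped (negative) part --
  ## the eigen-projection onto the PSD cone
  negs <- pmin(eigen(S, symmetric = TRUE, only.values = TRUE)$values, 0)
  expect_equal(norm(Sc - S, "F"), sqrt(sum(negs^2)), tolerance = 1e-10)

  expect_error(clipPSD(matrix(c(1, NA, NA, 1), 2, 2)), "finite")
})

test_that("Taylor surrogate reproduces its reference value and is exact
           for quadratic objectives", {
  quad <- syntheticSurface(seed = 18, bumpFraction = 0)
  traj <- vlaoOptimize(quad, defaultBounds(), tol = 1e-9)
  s <- taylorSurrogateAt(quad, traj@pStar)

  expect_equal(taylorEval(s, traj@pStar), s@f0, tolerance = 1e-12)

  ## Taylor expansion at the minimum of a quadratic is the function
  set.seed(19)
  for (i in 1:5) {
    p <- defaultBounds()@lower + runif(3) * (defaultBounds()@upper -
                                             defaultBounds()@lower)
    expect_equal(taylorEval(s, p), evalObjective(quad, p)$value,
                 tolerance = 1e-5)
  }

  ## bump surface: surrogate error is small near p* and grows outward
  bump <- syntheticSurface(seed = 18, bumpFraction = 0.1)
  trajB <- vlaoOptimize(bump, defaultBounds(), tol = 1e-9)
  sb <- taylorSurrogateAt(bump, trajB@pStar)
  dirn <- c(1, 1, 1) / sqrt(3)
  errAt <- function(r) abs(taylorEval(sb, trajB@pStar + r * dirn) -
                           evalObjective(bump, trajB@pStar + r * dirn)$value)
  expect_lt(errAt(0.05), 0.05)
  expect_gt(errAt(1.0), errAt(0.1))
})

test_that("trajectory-weighted surrogate interpolates its members", {
  bump <- syntheticSurface(seed = 20, bumpFraction = 0.1)
  traj <- vlaoOptimize(bump, defaultBounds())
  ts <- trajectorySurrogate(traj, bump, defaultBounds())
  expect_gte(length(ts@members), 1L)

  ## single member: identical to that member's Taylor value
  single <- new("TrajectorySurrogate", members = ts@members[1],
                bounds = defaultBounds(), epsilon = 1e-8)
  for (p in list(c(1.4, 2.4, 1.9), c(1.7, 3.1, 2.6)))
    expect_equal(weightedEval(single, p), taylorEval(ts@members[[1]], p),
                 tolerance = 1e-12)

  ## query on a trajectory point: the epsilon rule returns that member
  i <- length(ts@members)
  pi <- ts@members[[i]]@pStar
  expect_equal(weightedEval(ts, pi), taylorEval(ts@members[[i]], pi),
               tolerance = 1e-12)

  ## two members equidistant from the query: arithmetic mean
  mA <- taylorSurrogate(c(1.4, 2.5, 2.0), 1.0, c(0, 0, 0), diag(3))
  mB <- taylorSurrogate(c(1.8, 2.5, 2.0), 5.0, c(1, 0, 0), diag(3))
  pair <- new("TrajectorySurrogate", members = list(mA, mB),
              bounds = defaultBounds(), epsilon = 1e-8)
  pMid <- c(1.6, 2.5, 2.0)
  expect_equal(weightedEval(pair, pMid),
               (taylorEval(mA, pMid) + taylorEval(mB, pMid)) / 2,
               tolerance = 1e-12)
})

test_that("direct prediction is the backend itself and beats the Taylor
           model far from the reference point", {
  bump <- syntheticSurface(seed = 22, bumpFraction = 0.1)
  p <- c(1.45, 2.6, 2.1)
  expect_identical(predictDirect(bump, p), evalObjective(bump, p)$value)

  quad <- syntheticSurface(seed = 22, bumpFraction = 0)
  trajQ <- vlaoOptimize(quad, defaultBounds(), tol = 1e-9)
  sq <- taylorSurrogateAt(quad, trajQ@pStar)
  expect_equal(predictDirect(quad, p), taylorEval(sq, p), tolerance = 1e-5)

  trajB <- vlaoOptimize(bump, defaultBounds(), tol = 1e-9)
  sb <- taylorSurrogateAt(bump, trajB@pStar)
  far <- unname(defaultBounds()@upper)
  expect_gt(abs(predictDirect(bump, far) - taylorEval(sb, far)), 1e-3)
})

test_that("prediction error ordering over a ligand set is
           direct <= weighted <= single-point Taylor", {
  surf <- syntheticSurface(seed = 42, bumpFraction = 0.1, warp = 0)
  ligs <- syntheticLigandSet(surf, k = 21, seed = 42)
  tab <- buildDissociationTable(ligs, paste0("Fg", 1:16), surf)
  pca <- fitPCA(tab)
  bk <- pcaBackend(surf, pca)
  xs <- lapply(seq_len(nrow(tab)), function(i) toDescriptor(pca, tab[i, ]))
  prs <- projectAll(xs, bk, seed = 42)

  traj <- vlaoOptimize(surf, defaultBounds())
  sTay <- taylorSurrogateAt(surf, traj@pStar)
  sWgt <- trajectorySurrogate(traj, surf, defaultBounds())

  trueY <- vapply(ligs, function(l)
    evalObjective(surf, l$pTrue)$value, numeric(1))
  pHat <- lapply(prs, projectedParams)
  maeOf <- function(pred) mean(abs(pred - trueY))
  maeDirect <- maeOf(vapply(pHat, function(p) predictDirect(surf, p),
                            numeric(1)))
  maeWeighted <- maeOf(vapply(pHat, function(p) weightedEval(sWgt, p),
                              numeric(1)))
  maeTaylor <- maeOf(vapply(pHat, function(p) taylorEval(sTay, p),
                            numeric(1)))
  expect_lte(maeDirect, maeWeighted)
  expect_lte(maeWeighted, maeTaylor)
})
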