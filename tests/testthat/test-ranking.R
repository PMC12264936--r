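test_that("range-normalized deviation matches direct arithmetic", {
  b <- defaultBounds()
  pStar <- c(1.35, 2.13, 1.64)
  expect_identical(deltaPNorm(pStar, pStar, b), 0)

  ## one component displaced by its full range width -> exactly 1
  p <- pStar; p[2] <- p[2] + unname(b@upper - b@lower)[2]
  expect_equal(deltaPNorm(p, pStar, b), 1.0, tolerance = 1e-15)

  ## PEt3-like parameters vs the transmetalation reference point
  ## (frozen from an independent high-precision evaluation of the
  ## normalized-deviation formula)
  expect_equal(deltaPNorm(c(1.424, 2.620, 1.364), pStar, b), 0.3946874995,
               tolerance = 1e-9)

  expect_error(deltaPNorm(c(1, 2), pStar, b), "dimension")
})

test_that("reliability filters reproduce the reference strict and loose
           selections", {
  db <- ligandDatabase()
  b <- defaultBounds()
  pStar <- c(1.35, 2.13, 1.64)
  fl <- defaultFilters()

  strict <- applyFilter(db, pStar, b, fl$strict)
  expect_equal(nrow(strict), 6L)
  expect_setequal(strict$id, c("L7", "L10", "L11", "L12", "L18", "L20"))

  loose <- applyFilter(db, pStar, b, fl$loose)
  expect_equal(nrow(loose), 12L)
  ## loosening thresholds never removes a ligand
  expect_true(all(strict$id %in% loose$id))

  ## vanishing thresholds pass nothing (strict inequalities)
  none <- applyFilter(db, pStar, b, filterSpec(1e-9, 1e-9))
  expect_equal(nrow(none), 0L)
})

test_that("filter monotonicity holds across randomized thresholds", {
  db <- ligandDatabase()
  b <- defaultBounds()
  pStar <- c(1.35, 2.90, 1.62)
  set.seed(77)
  for (i in 1:20) {
    l1 <- runif(1, 0.5, 4); d1 <- runif(1, 0.2, 1.5)
    l2 <- l1 + runif(1, 0, 1); d2 <- d1 + runif(1, 0, 0.5)
    tight <- applyFilter(db, pStar, b, filterSpec(l1, d1))
    loose <- applyFilter(db, pStar, b, filterSpec(l2, d2))
    expect_true(all(tight$id %in% loose$id))
  }
})

test_that("ranking orders by predicted value with deterministic
           tie-breaks and flips with sense", {
  db <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                   r0 = c(1.5, 1.6, 1.7), a1 = c(2.5, 2.6, 2.7),
                   b1 = c(2.0, 2.1, 2.2), l_min = c(0.5, 0.6, 0.7),
                   stringsAsFactors = FALSE)
  b <- defaultBounds()
  pStar <- c(1.6, 2.6, 2.1)
  pred <- function(p) 10 * p[1]   # A < B < C
  wide <- list(all = filterSpec(10, 10, "all"))

  repMin <- rankLigands(db, pred, pStar = pStar, bounds = b,
                        sense = "minimize", filters = wide)
  expect_identical(rankTable(repMin)$rank_all, c(1L, 2L, 3L))
  repMax <- rankLigands(db, pred, pStar = pStar, bounds = b,
                        sense = "maximize", filters = wide)
  expect_identical(rankTable(repMax)$rank_all, c(3L, 2L, 1L))

  ## ties broken by smaller deviation from pStar, then id
  tied <- function(p) 1.0
  repTie <- rankLigands(db, tied, pStar = pStar, bounds = b,
                        sense = "minimize", filters = wide)
  tt <- rankTable(repTie)
  expect_identical(tt$id[order(tt$rank_all)],
                   tt$id[order(tt$dp_norm, tt$id)])

  ## byte-identical reports for identical inputs
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  writeRankingReport(repMin, f1)
  writeRankingReport(rankLigands(db, pred, pStar = pStar, bounds = b,
                                 sense = "minimize", filters = wide), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("trial order finds the true best ligand or flags it as
           filtered out", {
  db <- data.frame(id = c("A", "B", "C"), name = c("A", "B", "C"),
                   r0 = c(1.5, 1.6, 1.7), a1 = c(2.5, 2.6, 2.7),
                   b1 = c(2.0, 2.1, 2.2), l_min = c(0.5, 0.6, 0.7),
                   stringsAsFactors = FALSE)
  b <- defaultBounds()
  pStar <- c(1.6, 2.6, 2.1)
  wide <- list(all = filterSpec(10, 10, "all"))
  trueVals <- c(A = 3, B = 1, C = 2)   # B is the true best (minimize)

  ## perfect surrogate: true best is the first trial
  perfect <- function(p) trueVals[[c("A", "B", "C")[match(p[1],
                                                    c(1.5, 1.6, 1.7))]]]
  repP <- rankLigands(db, perfect, pStar = pStar, bounds = b,
                      sense = "minimize", filters = wide)
  expect_equal(trialOrder(repP, trueVals, "all")$position, 1L)

  ## anti-correlated surrogate on 3 ligands: found last
  anti <- function(p) -perfect(p)
  repA <- rankLigands(db, anti, pStar = pStar, bounds = b,
                      sense = "minimize", filters = wide)
  expect_equal(trialOrder(repA, trueVals, "all")$position, 3L)

  ## true best excluded by the filter: flagged, not ranked
  narrow <- list(tight = filterSpec(0.55, 10, "tight"))  # only A passes
  repF <- rankLigands(db, perfect, pStar = pStar, bounds = b,
                      sense = "minimize", filters = narrow)
  out <- trialOrder(repF, trueVals, "tight")
  expect_true(out$filteredOut)
  expect_identical(out$id, "B")
})

test_that("an end-to-end synthetic ranking places the true best ligand
           first when surrogate error is small", {
  surf <- syntheticSurface(seed = 30, bumpFraction = 0.05, warp = 0)
  ligs <- syntheticLigandSet(surf, k = 12, seed = 30)
  db <- buildParamDb(ligs, surf, seed = 30)

  trueY <- vapply(ligs, function(l)
    evalObjective(surf, l$pTrue)$value, numeric(1))

  ## direct prediction (no surrogate error): ranked first within a
  ## filter wide enough to keep everything
  wide <- list(all = filterSpec(100, 100, "all"))
  rep <- rankLigands(db, surf, pStar = c(1.6, 3.0, 2.0),
                     bounds = defaultBounds(), sense = "minimize",
                     filters = wide)
  out <- trialOrder(rep, trueY, "all")
  expect_false(out$filteredOut)
  expect_equal(out$position, 1L)
})
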