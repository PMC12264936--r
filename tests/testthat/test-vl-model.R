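test_that("keep potential is harmonic around r0 with exact gradients", {
  ## ideal geometry: all three bonds at r0 -> zero energy and force
  r0 <- 1.6
  dirs <- rbind(c(1, 0, -0.5), c(-0.5, 0.87, -0.5), c(-0.5, -0.87, -0.5))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  geom <- molecularGeometry(c("P", "Cl", "Cl", "Cl"),
                            rbind(c(0, 0, 0), r0 * dirs),
                            pIndex = 1L, clIndices = 2:4,
                            envIndices = integer(0))
  kp <- keepEnergy(geom, r0, kKeep = 100)
  expect_equal(kp$energy, 0, tolerance = 1e-12)
  expect_equal(max(abs(kp$gradient)), 0, tolerance = 1e-9)

  ## one bond displaced by delta -> E = kKeep * delta^2
  delta <- 0.07
  geom2 <- geom
  geom2@coords[2, ] <- (r0 + delta) * dirs[1, ]
  expect_equal(keepEnergy(geom2, r0, kKeep = 100)$energy, 100 * delta^2,
               tolerance = 1e-10)

  ## finite-difference oracle on randomized geometries
  for (seed in c(11, 23)) {
    g <- randomVLGeometry(seed)
    kp <- keepEnergy(g, 1.55, kKeep = 100)
    err <- fdGradError(function(x) keepEnergy(x, 1.55, 100)$energy,
                       g, kp$gradient)
    expect_lt(err, 1e-6)
  }
})

test_that("keep-angle potential matches its harmonic definition", {
  ## symmetric cone geometry with all three Cl-P-Cl angles at phi0
  phi0 <- 65
  cphi <- cos(phi0 * pi / 180)
  ct <- sqrt((cphi + 0.5) / 1.5)   # polar angle giving pairwise phi0
  st <- sqrt(1 - ct^2)
  dirs <- t(vapply(0:2, function(k) {
    az <- 2 * pi * k / 3
    c(st * cos(az), st * sin(az), ct)
  }, numeric(3)))
  geom <- molecularGeometry(c("P", "Cl", "Cl", "Cl"),
                            rbind(c(0, 0, 0), 1.7 * dirs),
                            pIndex = 1L, clIndices = 2:4,
                            envIndices = integer(0))
  ka <- keepAngleEnergy(geom, phi0, kAngle = 0.1)
  expect_equal(ka$energy, 0, tolerance = 1e-16)

  ## random geometry: energy equals the sum over measured angles
  g <- randomVLGeometry(31)
  xP <- g@coords[1, ]
  u <- lapply(2:4, function(i) {
    r <- g@coords[i, ] - xP; r / sqrt(sum(r^2))
  })
  angles <- c(acos(sum(u[[1]] * u[[2]])), acos(sum(u[[1]] * u[[3]])),
              acos(sum(u[[2]] * u[[3]]))) * 180 / pi
  expect_equal(keepAngleEnergy(g, phi0, 0.1)$energy,
               sum(0.1 * (angles - phi0)^2), tolerance = 1e-10)

  ## gradient against central finite differences
  for (seed in c(5, 17)) {
    g <- randomVLGeometry(seed)
    ka <- keepAngleEnergy(g, phi0, 0.1)
    err <- fdGradError(function(x) keepAngleEnergy(x, phi0, 0.1)$energy,
                       g, ka$gradient)
    expect_lt(err, 1e-6)
  }

  ## collinear Cl-P-Cl is flagged as degenerate
  bad <- molecularGeometry(c("P", "Cl", "Cl", "Cl"),
                           rbind(c(0, 0, 0), c(1.7, 0, 0), c(-1.7, 0, 0),
                                 c(0, 1.7, 0)),
                           pIndex = 1L, clIndices = 2:4,
                           envIndices = integer(0))
  expect_error(keepAngleEnergy(bad, phi0, 0.1), "collinear|degenerate")
})

test_that("ovoid LJ energy vanishes without environment atoms and is
           invariant under reflection in symmetric mode", {
  params <- vlParams(1.6, 3.0, 2.0)
  st <- fixedVLSettings()
  bare <- molecularGeometry(c("P", "Cl", "Cl", "Cl"),
                            randomVLGeometry(3)@coords[1:4, ],
                            pIndex = 1L, clIndices = 2:4,
                            envIndices = integer(0))
  expect_identical(ovoidLJEnergy(bare, params, st)$energy, 0)

  ## with a2 = a1 and b2 = b1 the ovoid is mirror-symmetric: reflecting
  ## the whole geometry through a plane leaves the energy unchanged
  g <- randomVLGeometry(13)
  e1 <- ovoidLJEnergy(g, params, st)$energy
  gm <- g; gm@coords[, 1] <- -gm@coords[, 1]
  expect_equal(ovoidLJEnergy(gm, params, st)$energy, e1,
               tolerance = 1e-10)
})

test_that("ovoid LJ gradients pass finite-difference checks", {
  params <- vlParams(1.6, 3.0, 2.0)
  st <- fixedVLSettings()
  for (seed in c(13, 29)) {
    g <- randomVLGeometry(seed)
    ov <- ovoidLJEnergy(g, params, st)
    err <- fdGradError(function(x) ovoidLJEnergy(x, params, st)$energy,
                       g, ov$gradient)
    expect_lt(err, 1e-5)
    h <- 1e-6
    fdA <- (ovoidLJEnergy(g, vlParams(1.6, 3.0 + h, 2.0), st)$energy -
            ovoidLJEnergy(g, vlParams(1.6, 3.0 - h, 2.0), st)$energy) /
           (2 * h)
    fdB <- (ovoidLJEnergy(g, vlParams(1.6, 3.0, 2.0 + h), st)$energy -
            ovoidLJEnergy(g, vlParams(1.6, 3.0, 2.0 - h), st)$energy) /
           (2 * h)
    expect_equal(ov$gradParams[["a1"]], fdA,
                 tolerance = 1e-5 * max(1, abs(fdA)))
    expect_equal(ov$gradParams[["b1"]], fdB,
                 tolerance = 1e-5 * max(1, abs(fdB)))
  }
})

test_that("total penalty is additive, linear in stiffness, and invariant
           under rigid motion", {
  params <- vlParams(1.55, 2.8, 1.9)
  st <- fixedVLSettings()
  g <- randomVLGeometry(41)

  total <- vlPenaltyEnergy(g, params, st)
  parts <- c(keepEnergy(g, params@r0, st@kKeep)$energy,
             keepAngleEnergy(g, st@phi0, st@kAngle)$energy,
             ovoidLJEnergy(g, params, st)$energy)
  expect_equal(total$energy, sum(parts), tolerance = 1e-12)
  expect_equal(unname(total$terms), parts, tolerance = 1e-12)

  ## at (r0, phi0)-ideal geometry with no environment atoms: zero
  phi0 <- 65; r0 <- 1.6
  cphi <- cos(phi0 * pi / 180); ct <- sqrt((cphi + 0.5) / 1.5)
  stq <- sqrt(1 - ct^2)
  dirs <- t(vapply(0:2, function(k)
    c(stq * cos(2 * pi * k / 3), stq * sin(2 * pi * k / 3), ct),
    numeric(3)))
  ideal <- molecularGeometry(c("P", "Cl", "Cl", "Cl"),
                             rbind(c(0, 0, 0), r0 * dirs),
                             pIndex = 1L, clIndices = 2:4,
                             envIndices = integer(0))
  expect_equal(vlPenaltyEnergy(ideal, vlParams(r0, 3, 2), st)$energy, 0,
               tolerance = 1e-16)

  ## doubling kKeep doubles exactly the keep contribution
  st2 <- fixedVLSettings(kKeep = 200)
  t2 <- vlPenaltyEnergy(g, params, st2)
  expect_equal(t2$terms[["keep"]], 2 * total$terms[["keep"]],
               tolerance = 1e-12)
  expect_equal(t2$terms[["keepAngle"]], total$terms[["keepAngle"]],
               tolerance = 1e-12)
  expect_equal(t2$terms[["ovoidLJ"]], total$terms[["ovoidLJ"]],
               tolerance = 1e-12)

  ## rigid rotation + translation leaves the energy unchanged
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  g2 <- g
  g2@coords <- g@coords %*% t(R) +
    matrix(c(1.2, -0.7, 2.5), nrow(g@coords), 3, byrow = TRUE)
  expect_equal(vlPenaltyEnergy(g2, params, st)$energy, total$energy,
               tolerance = 1e-9 * max(1, abs(total$energy)))
})
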