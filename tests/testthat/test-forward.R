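test_that("stick attenuation follows exp(-b d cos^2)", {
  t <- c(1, 0, 0)
  expect_equal(stickAttenuation(c(0, 1, 0), t, 1500, 1 / 1500), 1)
  expect_equal(stickAttenuation(t, t, 1500, 1 / 1500), exp(-1),
               tolerance = 1e-12)
  r45 <- directionFromAngles(0, 45)
  expect_equal(stickAttenuation(r45, t, 1500, 1 / 1500), exp(-0.5),
               tolerance = 1e-12)
  expect_error(stickAttenuation(t, t, -1, 1e-3), "non-negative")
})

test_that("predicted signal matches closed forms", {
  # pure ball
  prot <- dwiProtocol(cbind(c(0, 0, 0), c(1, 0, 0)), c(0, 1500))
  ball <- voxelModel(400, 1 / 1500)
  expect_equal(predictSignal(ball, prot), c(400, 400 * exp(-1)),
               tolerance = 1e-12)
  # two fibers in the XY-plane, gradient along Z
  m <- voxelModel(400, 1 / 1500, c(0.4, 0.5), theta = c(0, 0), phi = c(60, 120))
  protZ <- dwiProtocol(matrix(c(0, 0, 1)), 1500)
  expect_equal(predictSignal(m, protZ), 400 * (0.1 * exp(-1) + 0.9),
               tolerance = 1e-10)
  bad <- m; bad@fractions <- c(0.6, 0.6)
  expect_error(predictSignal(bad, protZ), "at most 1")
})

test_that("dot-product form agrees with the explicit rotation-matrix form", {
  sc <- makeScenario("paper-default-64")
  m <- sc$model
  keep <- !isHypothetical(sc$protocol)
  b <- bValues(sc$protocol)[keep]
  U <- gradientDirections(sc$protocol)[, keep]
  A <- diag(c(1, 0, 0))
  oracle <- (1 - sum(m@fractions)) * exp(-b * m@d)
  for (k in 1:2) {
    Rk <- basisWithFirstColumn(m@orientations[, k])
    q <- vapply(seq_along(b), function(i)
      drop(t(U[, i]) %*% Rk %*% A %*% t(Rk) %*% U[, i]), 0)
    oracle <- oracle + m@fractions[k] * exp(-b * m@d * q)
  }
  expect_equal(predictSignal(m, sc$protocol), 400 * oracle, tolerance = 1e-10)
})

test_that("simplified signal equals the full model after rotation", {
  set.seed(11)
  prot <- tinyProtocol(nB0 = 0L)
  for (i in 1:100) {
    axis <- drop(randomAxes(1, seed = i))
    R <- rotationToZ(axis)
    phi <- sort(runif(2, 0, pi))
    F <- runif(1, 0.3, 0.95); f1 <- runif(1, 0, F)
    d <- runif(1, 0.3, 3) / 1500
    fibers <- t(R) %*% rbind(cos(phi), sin(phi), 0)
    m <- voxelModel(400, d, c(f1, F - f1), orientations = fibers)
    nu <- new("NuisanceEstimates", S0 = 400, d = d, F = F,
              axis = axis, rotation = R)
    full <- predictSignal(m, prot)
    simp <- predictSignalSimplified(f1, phi[1L], phi[2L], nu,
                                    R %*% gradientDirections(prot),
                                    bValues(prot))
    expect_equal(simp, full, tolerance = 1e-10)
  }
})

test_that("simplified signal degenerates and symmetrizes correctly", {
  prot <- tinyProtocol(nB0 = 1L)
  axis <- c(0, 0, 1)
  nu <- new("NuisanceEstimates", S0 = 400, d = 1 / 1500, F = 0.9,
            axis = axis, rotation = diag(3))
  rb <- gradientDirections(prot); bv <- bValues(prot)
  # f1 = F: second stick vanishes -> one-stick model
  one <- voxelModel(400, 1 / 1500, 0.9, theta = 0, phi = 30)
  expect_equal(predictSignalSimplified(0.9, 30 * pi / 180, 2, nu, rb, bv),
               predictSignal(one, prot), tolerance = 1e-10)
  # coincident azimuths: signal independent of the split
  expect_equal(predictSignalSimplified(0.2, 1, 1, nu, rb, bv),
               predictSignalSimplified(0.7, 1, 1, nu, rb, bv),
               tolerance = 1e-12)
  expect_error(predictSignalSimplified(0.95, 1, 2, nu, rb, bv), "f1")
})

test_that("noise injection is seeded, unbiased and correctly scaled", {
  s <- rep(100, 10)
  expect_identical(addNoise(s, 0), s)
  expect_identical(addNoise(s, 5, seed = 3), addNoise(s, 5, seed = 3))
  draws <- addNoise(rep(0, 1e5), 7, seed = 1)
  expect_equal(sd(draws), 7, tolerance = 0.02)
  expect_lt(abs(mean(draws)), 7 * 3 / sqrt(1e5))
})

test_that("scenario registry returns the documented conditions", {
  sc <- makeScenario("paper-default-64")
  expect_equal(sum(bValues(sc$protocol) > 0 & !isHypothetical(sc$protocol)), 64L)
  expect_equal(sc$model@sigma, 20)
  expect_equal(sc$model@S0, 400)
  expect_equal(sc$model@d * 1500, 1, tolerance = 1e-12)
  ang <- anglesFromDirection(sc$model@orientations)
  expect_equal(ang$phi, c(60, 120)); expect_equal(ang$theta, c(0, 0))
  sc3 <- makeScenario("threefiber-3")
  expect_equal(sc3$model@fractions, rep(0.25, 3))
  expect_equal(angularSeparation(sc3$model@orientations[, 3], c(0, 0, 1)), 0,
               tolerance = 1e-9)
  expect_error(makeScenario("nope"), "paper-default-64")
  expect_equal(makeScenario("paper-default-64", sigma = 0)$model@sigma, 0)
  expect_error(voxelModel(400, 1 / 1500, c(0.7, 0.5), theta = c(0, 0),
                          phi = c(0, 90)), "at most 1")
})

test_that("signal is antipodally symmetric and rotation equivariant", {
  m <- makeScenario("paper-default-64")$model
  U <- randomAxes(20, seed = 5)
  protA <- dwiProtocol(U, rep(1500, 20))
  protB <- dwiProtocol(-U, rep(1500, 20))
  expect_equal(predictSignal(m, protA), predictSignal(m, protB),
               tolerance = 1e-12)
  for (i in 1:5) {
    M <- matrix(rnorm(9), 3); Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    m2 <- voxelModel(m@S0, m@d, m@fractions, orientations = Q %*% m@orientations,
                     sigma = 0)
    prot2 <- dwiProtocol(Q %*% U, rep(1500, 20))
    expect_equal(predictSignal(m2, prot2), predictSignal(m, protA),
                 tolerance = 1e-10)
  }
})

test_that("the noiseless maximum lies along the fibers' common perpendicular", {
  m <- makeScenario("paper-default-64")$model
  grid <- generateUniformDirections(400)
  prot <- dwiProtocol(grid, rep(1500, 400))
  s <- predictSignal(m, prot)
  best <- grid[, which.max(s)]
  expect_lt(angularSeparation(best, c(0, 0, 1)), 8)
})
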