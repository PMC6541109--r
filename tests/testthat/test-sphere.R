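test_that("direction angles follow the elevation convention", {
  expect_equal(directionFromAngles(0, 0), c(1, 0, 0), tolerance = 1e-12)
  expect_equal(directionFromAngles(90, 0), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(directionFromAngles(90, 123), c(0, 0, 1), tolerance = 1e-12)
  expect_equal(directionFromAngles(0, 60), c(0.5, sqrt(3) / 2, 0),
               tolerance = 1e-12)
  expect_error(directionFromAngles(NA, 0), "finite")
})

test_that("angles round-trip through directions up to antipodal equivalence", {
  set.seed(4)
  th <- runif(50, -90, 90); ph <- runif(50, 0, 360)
  U <- directionFromAngles(th, ph)
  a <- anglesFromDirection(U)
  U2 <- directionFromAngles(a$theta, a$phi)
  expect_lt(max(angularSeparation(U, U2, axial = TRUE)), 1e-7)
})

test_that("angular separation handles identity, antipodes and orthogonality", {
  u <- c(1, 0, 0)
  expect_equal(angularSeparation(u, u), 0)
  expect_equal(angularSeparation(u, -u, axial = TRUE), 0)
  expect_equal(angularSeparation(u, -u, axial = FALSE), 180)
  expect_equal(angularSeparation(u, c(0, 1, 0)), 90)
  expect_error(angularSeparation(u, c(0, 0, 0)), "zero")
})

test_that("polar angular separation is symmetric and metric-like", {
  U <- randomAxes(30, seed = 7)
  for (i in 1:10) {
    a <- U[, 3 * i - 2]; b <- U[, 3 * i - 1]; c <- U[, 3 * i]
    dab <- angularSeparation(a, b, axial = FALSE)
    dba <- angularSeparation(b, a, axial = FALSE)
    expect_equal(dab, dba, tolerance = 1e-10)
    expect_lte(dab,
               angularSeparation(a, c, axial = FALSE) +
                 angularSeparation(c, b, axial = FALSE) + 1e-8)
  }
})

test_that("rotationToZ maps any axis onto +Z and is a proper rotation", {
  expect_equal(rotationToZ(c(0, 0, 1)), diag(3), tolerance = 1e-12)
  U <- randomAxes(1000, seed = 2)
  for (i in seq_len(ncol(U))) {
    R <- rotationToZ(U[, i])
    expect_lt(max(abs(R %*% U[, i] - c(0, 0, 1))), 1e-10)
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-10)
    expect_equal(det(R), 1, tolerance = 1e-10)
  }
  # inverse available as transpose
  v <- c(0.3, -0.5, 0.8); v <- v / sqrt(sum(v^2))
  R <- rotationToZ(randomAxes(1, seed = 9))
  expect_equal(drop(t(R) %*% (R %*% v)), v, tolerance = 1e-12)
})

test_that("uniform direction schemes are unit, spread and deterministic", {
  U <- generateUniformDirections(64)
  expect_equal(dim(U), c(3L, 64L))
  expect_lt(max(abs(sqrt(colSums(U^2)) - 1)), 1e-12)
  C <- abs(crossprod(U)); ang <- acos(pmin(C, 1)) * 180 / pi; diag(ang) <- Inf
  expect_gt(min(ang), 10)                       # brute-force pairwise check
  expect_identical(U, generateUniformDirections(64))
  expect_identical(generateUniformDirections(16, seed = 5, iterations = 50),
                   generateUniformDirections(16, seed = 5, iterations = 50))
  expect_error(generateUniformDirections(5), "at least 6")
})

test_that("hypothetical directions are a rigid rotation filling scheme gaps", {
  obs <- generateUniformDirections(32)
  H <- generateHypotheticalDirections(obs, seed = 1L, nCandidates = 200L)
  # rigid rotation preserves all pairwise axial separations
  expect_equal(abs(crossprod(H)), abs(crossprod(obs)), tolerance = 1e-9)
  # maximin objective: at least as good as 20 random alternative rotations
  maximin <- function(A, B) {
    C <- abs(crossprod(A, B))
    min(acos(pmin(apply(C, 1L, max), 1))) * 180 / pi
  }
  achieved <- maximin(H, obs)
  set.seed(99)
  for (i in 1:20) {
    M <- matrix(rnorm(9), 3); Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 3] <- -Q[, 3]
    expect_gte(achieved, maximin(Q %*% obs, obs) - 1e-9)
  }
})

test_that("the combined 64+64 scheme improves angular resolution", {
  prot <- makeScenario("paper-default-64")$protocol
  dw <- bValues(prot) > 0
  All <- gradientDirections(prot)[, dw]
  obs <- All[, !isHypothetical(prot)[dw]]
  nnMax <- function(M) {
    A <- acos(pmin(abs(crossprod(M)), 1)) * 180 / pi; diag(A) <- Inf
    max(apply(A, 1L, min))
  }
  expect_equal(ncol(All), 128L)
  # hypothetical insertion shrinks the largest angular gap well below the
  # observed scheme's own spacing
  expect_lt(nnMax(All), 12)
  expect_lt(nnMax(All), nnMax(obs) - 3)
})

test_that("bval/bvec files round-trip and validate", {
  prot <- tinyProtocol()
  bval <- tempfile(fileext = ".bval"); bvec <- tempfile(fileext = ".bvec")
  writeBvalBvec(prot, bval, bvec)
  prot2 <- readBvalBvec(bval, bvec)
  expect_equal(bValues(prot2), bValues(prot))
  expect_equal(gradientDirections(prot2), gradientDirections(prot),
               tolerance = 1e-9)
  writeLines(c("1 2", "3 4"), bvec)                  # only two rows
  expect_error(readBvalBvec(bval, bvec), "three rows")
  writeLines(c("1 0", "0 1", "0 0"), bvec)           # length mismatch
  expect_error(readBvalBvec(bval, bvec), "number of acquisitions")
})
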