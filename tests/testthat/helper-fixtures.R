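# Shared fixtures, built in code.  The registered scenario protocols are
# memoized inside the package, so repeated makeScenario() calls are cheap.

# a tiny 6-direction single-shell protocol for fast structural tests
tinyProtocol <- function(nB0 = 1L, b = 1500) {
  U <- generateUniformDirections(6L)
  dwiProtocol(cbind(matrix(0, 3L, nB0), U), c(rep(0, nB0), rep(b, 6L)))
}

# random unit vectors, seeded
randomAxes <- function(n, seed = 1L) {
  set.seed(seed)
  U <- matrix(rnorm(3L * n), 3L)
  sweep(U, 2L, sqrt(colSums(U^2)), "/")
}

# orthonormal matrix with a given first column (for the matrix-form oracle)
basisWithFirstColumn <- function(t1) {
  t1 <- t1 / sqrt(sum(t1^2))
  a <- if (abs(t1[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- a - sum(a * t1) * t1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(t1[2L] * e2[3L] - t1[3L] * e2[2L],
          t1[3L] * e2[1L] - t1[1L] * e2[3L],
          t1[1L] * e2[2L] - t1[2L] * e2[1L])
  cbind(t1, e2, e3)
}

# short simplified-model configuration for unit tests
fastConfig <- function(seed = 1L, nIter = 10000L)
  mcmcConfig(nIter = nIter, thin = 5L, seed = seed)
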