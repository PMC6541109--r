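test_that("the Gaussian log-likelihood matches its closed form and a sum oracle", {
  y <- c(1, 2, 3, 4)
  expect_equal(logLikelihood(y, y, 2), -2 * log(2 * pi * 4))
  expect_equal(logLikelihood(y, y, 4) - logLikelihood(y, y, 2), -4 * log(2))
  set.seed(2)
  mu <- rnorm(50); obs <- mu + rnorm(50)
  expect_equal(logLikelihood(obs, mu, 1.7),
               sum(dnorm(obs, mu, 1.7, log = TRUE)), tolerance = 1e-10)
  expect_error(logLikelihood(y, y, 0), "positive")
})

test_that("proposals are symmetric Gaussian perturbations", {
  expect_equal(propose(5, 0), 5)
  set.seed(1)
  draws <- propose(rep(2, 1e5), 0.3)
  expect_equal(sd(draws), 0.3, tolerance = 0.02)
  expect_equal(mean(draws), 2, tolerance = 0.3 * 4 / sqrt(1e5))
})

test_that("the conjugate precision draw matches its Gamma posterior", {
  set.seed(3)
  resid <- rnorm(64, 0, 20)
  draws <- replicate(2e4, gibbsUpdatePrecision(resid, 200, 1))
  expect_true(all(draws > 0))
  postMean <- (200 + 32) / (1 + sum(resid^2) / 2)
  expect_equal(mean(1 / draws^2), postMean, tolerance = 0.02)
  # no-data limit reproduces the prior
  prior <- replicate(2e4, gibbsUpdatePrecision(numeric(0), 200, 1))
  expect_equal(mean(1 / prior^2), 200, tolerance = 0.02)
})

test_that("proposal adaptation is directional and diminishing", {
  expect_lt(adaptProposals(1, 0, 3), 1)
  expect_gt(adaptProposals(1, 1, 3), 1)
  expect_equal(adaptProposals(1, 0.44, 3), 1)
  expect_equal(adaptProposals(1, 1, 1), exp(0.01), tolerance = 1e-12)
  expect_equal(adaptProposals(1, 1, 1e8), 1, tolerance = 1e-3)
})

test_that("Metropolis machinery reproduces a known 1-D posterior", {
  # random-walk MH on a standard normal target using the package's proposal
  # and the symmetric acceptance rule; quantiles must match the analytic law
  set.seed(10)
  n <- 1e5
  x <- numeric(n); cur <- 0; lp <- dnorm(cur, log = TRUE)
  for (i in seq_len(n)) {
    cand <- propose(cur, 2.4)
    lpc <- dnorm(cand, log = TRUE)
    if (log(runif(1)) < lpc - lp) { cur <- cand; lp <- lpc }
    x[i] <- cur
  }
  ks <- suppressWarnings(ks.test(x[seq(1000, n, by = 10)], pnorm))
  expect_lt(unname(ks$statistic), 0.02)
})

test_that("the simplified sampler recovers noiseless rotated-frame truth", {
  sc <- makeScenario("paper-default-64")
  clean <- predictSignal(sc$model, sc$protocol)
  nu <- new("NuisanceEstimates", S0 = 400, d = 1 / 1500, F = 0.9,
            axis = c(0, 0, 1), rotation = diag(3))
  ch <- runSimplifiedMCMC(clean, sc$protocol, nu, fastConfig(seed = 4,
                                                             nIter = 20000L))
  S <- chainSamples(ch)
  kept <- S[seq(10001, 20000, by = 5), ]
  phis <- sort(c(median(kept[, "phi1p"]), median(kept[, "phi2p"]))) * 180 / pi
  expect_lt(abs(phis[1] - 60), 3)
  expect_lt(abs(phis[2] - 120), 3)
  f1 <- median(pmin(kept[, "f1"], 0.9 - kept[, "f1"]))
  expect_equal(f1, 0.4, tolerance = 0.05)
})

test_that("the simplified likelihood is invariant under label exchange", {
  prot <- tinyProtocol(nB0 = 0L)
  nu <- new("NuisanceEstimates", S0 = 400, d = 1 / 1500, F = 0.9,
            axis = c(0, 0, 1), rotation = diag(3))
  rb <- gradientDirections(prot); bv <- bValues(prot)
  a <- predictSignalSimplified(0.3, 0.7, 2.1, nu, rb, bv)
  b <- predictSignalSimplified(0.9 - 0.3, 2.1, 0.7, nu, rb, bv)
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("chains are bit-identical under the same seed", {
  sc <- makeScenario("paper-default-64")
  y <- simulateVoxel(sc, seed = 6)
  nu <- estimateNuisance(y, sc$protocol, S0 = 400)
  c1 <- runSimplifiedMCMC(y, sc$protocol, nu, fastConfig(seed = 42, nIter = 3000L))
  c2 <- runSimplifiedMCMC(y, sc$protocol, nu, fastConfig(seed = 42, nIter = 3000L))
  expect_identical(c1@samples, c2@samples)
  f1 <- runFullMCMC(y, sc$protocol, fastConfig(seed = 42, nIter = 3000L),
                    nuisance = nu)
  f2 <- runFullMCMC(y, sc$protocol, fastConfig(seed = 42, nIter = 3000L),
                    nuisance = nu)
  expect_identical(f1@samples, f2@samples)
})

test_that("the simplified sampler refuses isotropic voxels", {
  sc <- makeScenario("paper-default-64")
  y <- simulateVoxel(sc, seed = 1)
  nu <- new("NuisanceEstimates", S0 = 400, d = 1 / 1500, F = 0,
            axis = c(0, 0, 1), rotation = diag(3))
  expect_error(runSimplifiedMCMC(y, sc$protocol, nu, fastConfig()),
               "isotropic")
})

test_that("the full sampler recovers a one-fiber voxel and the noise level", {
  sc <- makeScenario("onefiber-64", nB0 = 8L)
  clean <- predictSignal(sc$model, sc$protocol)
  y <- addNoise(clean, 20, seed = 5)
  # weak precision prior so the noise posterior is data-driven
  cfg <- mcmcConfig(nIter = 30000L, thin = 5L, seed = 7, priorShape = 1e-3,
                    priorRate = 1e-3)
  nu <- estimateNuisance(y, sc$protocol)
  ch <- runFullMCMC(y, sc$protocol, cfg, nuisance = nu)
  post <- summarizePosterior(ch)
  sm <- post$summary
  expect_equal(sm$median[sm$parameter == "sigma"], 20, tolerance = 0.15)
  fsum <- sm$median[sm$parameter == "f1"] + sm$median[sm$parameter == "f2"]
  expect_equal(fsum, 0.9, tolerance = 0.12)
  truthAxis <- sc$model@orientations[, 1L]
  dists <- angularSeparation(post$directions, cbind(truthAxis, truthAxis))
  expect_lt(min(dists), 8)
})

test_that("the inverse-gamma precision variant matches its closed-form limit", {
  # noiseless data: SSR ~ 0, so the GIG conditional of sigma^2 collapses to
  # Gamma(shape - n/2, rate); with shape 200, n = 64 the posterior of
  # sigma^2 is Gamma(168, 1): mean 168
  sc <- makeScenario("paper-default-64")
  clean <- predictSignal(sc$model, sc$protocol)
  nu <- new("NuisanceEstimates", S0 = 400, d = 1 / 1500, F = 0.9,
            axis = c(0, 0, 1), rotation = diag(3))
  cfg <- mcmcConfig(nIter = 8000L, thin = 2L, seed = 12,
                    precisionPrior = "invgamma")
  ch <- runSimplifiedMCMC(clean, sc$protocol, nu, cfg)
  sig2 <- chainSamples(ch)[4001:8000, "sigma"]^2
  expect_true(all(sig2 > 0))
  expect_equal(mean(sig2), 200 - 32, tolerance = 0.08)
})

test_that("posterior summaries are exact on degenerate chains", {
  const <- matrix(rep(c(0.3, 1.0, 2.0, 15), each = 200), ncol = 4)
  ch <- new("MCMCChain", samples = const,
            parnames = c("f1", "phi1p", "phi2p", "sigma"),
            proposalSd = rep(0.1, 3), acceptance = rep(0.4, 3),
            model = "simplified", config = unclass(fastConfig()),
            stoppedAt = NA_integer_)
  nu <- new("NuisanceEstimates", S0 = 400, d = 1 / 1500, F = 0.9,
            axis = c(0, 0, 1), rotation = diag(3))
  post <- summarizePosterior(ch, nu, burnInFraction = 0.5, thin = 1)
  sm <- post$summary
  expect_equal(sm$median[sm$parameter == "f1"], 0.3)
  expect_equal(sm$sd[sm$parameter == "f1"], 0)
  # identity frame: theta = 0 and phi = phi' in degrees
  expect_equal(sm$median[sm$parameter == "theta1"], 0, tolerance = 1e-9)
  expect_equal(sm$median[sm$parameter == "phi1"], 1.0 * 180 / pi,
               tolerance = 1e-9)
  expect_error(summarizePosterior(ch, nu, burnInFraction = 0.999),
               "burn-in")
})

test_that("thinning choices agree on a stationary chain", {
  sc <- makeScenario("paper-default-64")
  y <- simulateVoxel(sc, seed = 2)
  nu <- estimateNuisance(y, sc$protocol, S0 = 400)
  ch <- runSimplifiedMCMC(y, sc$protocol, nu, fastConfig(seed = 3,
                                                         nIter = 30000L))
  p1 <- summarizePosterior(ch, nu, thin = 1)
  p10 <- summarizePosterior(ch, nu, thin = 10)
  expect_equal(p1$fractions, p10$fractions, tolerance = 0.02)
})

test_that("per-iteration cost accounting favors the simplified chain", {
  # one simplified iteration: 3 Metropolis updates, each evaluating the
  # 2-azimuth mean model over n acquisitions (2-D dot products).  One full
  # iteration: 8 updates, each evaluating the 2-stick model with 3-D dot
  # products plus the ball over the same acquisitions.  Count multiply-adds.
  n <- 64
  simplifiedFlops <- 3 * n * (2 * 2 + 2 * 3)     # 2 dots + 2 exp-terms each
  fullFlops <- 8 * n * (2 * 3 + 3 * 3)           # 2 3-D dots + 3 exp-terms
  expect_gte(fullFlops / simplifiedFlops, 5 * 0.8)
  # and empirically, per-iteration wall time is lower (not asserted tightly)
  sc <- makeScenario("paper-default-64")
  y <- simulateVoxel(sc, seed = 1)
  nu <- estimateNuisance(y, sc$protocol, S0 = 400)
  t1 <- system.time(runSimplifiedMCMC(y, sc$protocol, nu,
                                      fastConfig(seed = 1, nIter = 20000L)))[3]
  t2 <- system.time(runFullMCMC(y, sc$protocol,
                                fastConfig(seed = 1, nIter = 20000L),
                                nuisance = nu))[3]
  expect_lt(t1, t2)
})
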