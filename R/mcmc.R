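# Adaptive Metropolis-within-Gibbs estimation of the simplified and full
# Ball-and-Stick models, plus posterior summarization with back-rotation.

#' MCMC configuration
#'
#' @param nIter total iterations (default 1e5).
#' @param burnInFraction fraction of the chain discarded before
#'   summarization (default 0.5).
#' @param thin keep every thin-th post-burn-in draw (default 10).
#' @param adaptInterval iterations per proposal-adaptation batch (default 50).
#' @param targetAccept target Metropolis acceptance rate (default 0.44, the
#'   optimal rate for one-dimensional random-walk updates).
#' @param seed integer seed; NULL continues the current RNG stream.
#' @param precisionPrior prior on the noise precision sigma^-2:
#'   "gamma" (default) is the conjugate Gamma(shape, rate) prior on the
#'   precision with a closed-form Gibbs draw; "invgamma" places an
#'   Inverse-Gamma(shape, scale) density on the precision itself, whose
#'   conditional is generalized-inverse-Gaussian, updated by a
#'   slice-sampling step on log(sigma^2).
#' @param priorShape,priorRate hyperparameters of either prior (default
#'   200 and 1).
#' @param stopping optional \code{\link{stoppingRule}} enabling dynamic
#'   stopping via the Geweke diagnostic; NULL runs the full nIter.
#' @return a list of class "mcmcConfig".
#' @export
mcmcConfig <- function(nIter = 100000L, burnInFraction = 0.5, thin = 10L,
                       adaptInterval = 50L, targetAccept = 0.44, seed = NULL,
                       precisionPrior = c("gamma", "invgamma"),
                       priorShape = 200, priorRate = 1, stopping = NULL) {
  if (burnInFraction <= 0 || burnInFraction >= 1)
    stop("burnInFraction must be in (0, 1)")
  if (thin < 1L) stop("thin must be >= 1")
  if (adaptInterval < 10L) stop("adaptInterval must be >= 10")
  structure(list(nIter = as.integer(nIter), burnInFraction = burnInFraction,
                 thin = as.integer(thin), adaptInterval = as.integer(adaptInterval),
                 targetAccept = targetAccept, seed = seed,
                 precisionPrior = match.arg(precisionPrior),
                 priorShape = priorShape, priorRate = priorRate,
                 stopping = stopping),
            class = "mcmcConfig")
}

#' Gaussian log-likelihood of a predicted signal
#'
#' -n/2 log(2 pi sigma^2) - SSR / (2 sigma^2).
#'
#' @param observed,predicted aligned numeric vectors.
#' @param sigma noise standard deviation, > 0.
#' @return scalar log density.
#' @export
logLikelihood <- function(observed, predicted, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  n <- length(observed)
  -n / 2 * log(2 * pi * sigma^2) - sum((observed - predicted)^2) / (2 * sigma^2)
}

#' Symmetric Gaussian random-walk proposal
#'
#' @param current current parameter value(s).
#' @param epsilon proposal standard deviation(s).
#' @return candidate value(s); symmetric, so the Metropolis ratio reduces to
#'   the posterior ratio.
#' @export
propose <- function(current, epsilon) {
  if (any(epsilon < 0)) stop("epsilon must be non-negative")
  current + rnorm(length(current), 0, epsilon)
}

#' Conjugate Gibbs draw of the noise standard deviation
#'
#' Under a Gamma(shape, rate) prior on the precision the full conditional is
#' Gamma(shape + n/2, rate + SSR/2); returns sigma = precision^(-1/2).
#'
#' @param residuals residual vector at the current parameter values.
#' @param priorShape,priorRate Gamma prior hyperparameters.
#' @return a draw of sigma.
#' @export
gibbsUpdatePrecision <- function(residuals, priorShape, priorRate) {
  tau <- rgamma(1L, shape = priorShape + length(residuals) / 2,
                rate = priorRate + sum(residuals^2) / 2)
  1 / sqrt(tau)
}

#' Diminishing proposal-scale adaptation
#'
#' Every batch the per-parameter scale is multiplied by delta when the batch
#' acceptance rate exceeds the target, divided by delta when below, and left
#' unchanged at exactly the target, with
#' delta = exp(min(0.01, 1/sqrt(batchIndex))) so the adaptation vanishes.
#'
#' @param epsilon current proposal sd(s).
#' @param acceptRate batch acceptance rate(s), same length.
#' @param batchIndex 1-based batch counter.
#' @param target target acceptance rate (default 0.44).
#' @return updated proposal sd(s).
#' @export
adaptProposals <- function(epsilon, acceptRate, batchIndex, target = 0.44) {
  delta <- exp(min(0.01, 1 / sqrt(batchIndex)))
  ifelse(acceptRate > target, epsilon * delta,
         ifelse(acceptRate < target, epsilon / delta, epsilon))
}

# deterministic starting azimuths: coarse grid scan of the rotated-frame
# residual with f1 = F/2 over all azimuth pairs
.initAzimuths <- function(y, rx, ry, bd, S0, Ftot, nGrid = 36L) {
  g <- (seq_len(nGrid) - 1L) * pi / nGrid
  A <- exp(-bd * (outer(rx, cos(g)) + outer(ry, sin(g)))^2)   # n x nGrid
  base <- y - S0 * (1 - Ftot) * exp(-bd)
  B <- S0 * (Ftot / 2) * A
  M <- crossprod(B)
  v <- drop(crossprod(B, base))
  ssr <- -2 * outer(v, v, "+") + outer(diag(M), diag(M), "+") + 2 * M
  ssr[upper.tri(ssr, diag = TRUE)] <- Inf     # keep ordered distinct pairs
  idx <- arrayInd(which.min(ssr), dim(ssr))
  if (!is.finite(ssr[idx])) return(c(pi / 4, 3 * pi / 4))
  sort(c(g[idx[1L]], g[idx[2L]]))
}

.precType <- function(config) if (config$precisionPrior == "gamma") 0L else 1L

# run a chain in segments, checking the Geweke-based stopping rule between
# segments when enabled
.runSegmented <- function(stepFun, init, eps, config) {
  rule <- config$stopping
  nIter <- config$nIter
  if (is.null(rule)) {
    out <- stepFun(init, eps, nIter, 0L)
    return(list(samples = out$samples, eps = out$eps, accept = out$accept,
                stoppedAt = NA_integer_))
  }
  seg <- rule$checkInterval
  samples <- NULL; acc <- NULL
  done <- 0L
  repeat {
    take <- min(seg, nIter - done)
    out <- stepFun(init, eps, take, done %/% config$adaptInterval)
    samples <- rbind(samples, out$samples)
    eps <- out$eps
    acc <- if (is.null(acc)) out$accept * take else acc + out$accept * take
    done <- done + take
    init <- samples[nrow(samples), ]   # same layout: parameters then sigma
    if (done >= nIter) break
    if (done >= rule$minIterations) {
      dec <- shouldStop(samples, rule, iteration = done)
      if (dec$stop) break
    }
  }
  list(samples = samples, eps = eps, accept = acc / done, stoppedAt = done)
}

#' Run the adaptive sampler for the simplified two-fiber model
#'
#' Samples (f1, phi'1, phi'2, sigma) for the rotated-frame simplified model,
#' conditioning on the stage-one nuisance estimates: the gradients are mapped
#' through the longitudinal-axis rotation before likelihood evaluation, and
#' f2 = F - f1 by construction.  f1 has uniform support [0, F] (so f2 >= 0)
#' and the azimuths uniform support [0, pi); out-of-support proposals are
#' rejected through the prior.  Starting values are deterministic: f1 = F/2,
#' azimuths from a coarse grid scan of the rotated-frame residual, sigma at
#' 5 percent of S0.
#'
#' @param signal observed signal vector.
#' @param protocol a \code{\link{DWIProtocol}}.
#' @param nuisance a \code{\link{NuisanceEstimates}}.
#' @param config an \code{\link{mcmcConfig}}.
#' @return an \code{\link{MCMCChain}}.
#' @export
runSimplifiedMCMC <- function(signal, protocol, nuisance, config = mcmcConfig()) {
  if (nuisance@F <= 0)
    stop("total stick fraction is zero: voxel is isotropic; ",
         "fit a one-fiber/isotropic model instead")
  if (!is.null(config$seed)) set.seed(config$seed)
  keep <- !isHypothetical(protocol)
  b <- bValues(protocol)[keep]
  Rb <- nuisance@rotation %*% gradientDirections(protocol)[, keep, drop = FALSE]
  bd <- b * nuisance@d
  dw <- b > 0
  phis <- .initAzimuths(signal[dw], Rb[1L, dw], Rb[2L, dw], bd[dw],
                        nuisance@S0, nuisance@F)
  init <- c(nuisance@F / 2, phis, 0.05 * nuisance@S0)
  eps0 <- c(0.05 * max(nuisance@F, 0.1), 0.1, 0.1)
  stepFun <- function(ini, eps, nIter, batchOffset)
    .cpp_run_simplified(signal, Rb[1L, ], Rb[2L, ], bd, nuisance@S0,
                        nuisance@F, ini, eps, as.integer(nIter),
                        config$adaptInterval, config$targetAccept,
                        .precType(config), config$priorShape, config$priorRate,
                        as.integer(batchOffset))
  out <- .runSegmented(stepFun, init, eps0, config)
  new("MCMCChain", samples = out$samples,
      parnames = c("f1", "phi1p", "phi2p", "sigma"),
      proposalSd = out$eps, acceptance = out$accept,
      model = "simplified", config = unclass(config), stoppedAt = out$stoppedAt)
}

#' Run the adaptive sampler for the full nine-parameter model
#'
#' Samples (S0, d, f1, f2, theta1, phi1, theta2, phi2, sigma) of the full
#' two-fiber Ball-and-Stick model with the same adaptive
#' Metropolis-within-Gibbs machinery as the simplified sampler.  Priors are
#' weakly informative uniforms: S0 ~ U(0, 2 max signal), d ~ U(1e-5, 1e-2)
#' mm^2/s, f1, f2 ~ U(0,1) restricted to f1 + f2 <= 1, azimuths uniform on
#' [0, 2 pi), elevations area-uniform (density proportional to cos theta).
#' Started at the stage-one estimates when supplied.
#'
#' @param signal observed signal vector.
#' @param protocol a \code{\link{DWIProtocol}}.
#' @param config an \code{\link{mcmcConfig}}.
#' @param nuisance optional \code{\link{NuisanceEstimates}} for starting
#'   values.
#' @return an \code{\link{MCMCChain}}.
#' @export
runFullMCMC <- function(signal, protocol, config = mcmcConfig(), nuisance = NULL) {
  if (!is.null(config$seed)) set.seed(config$seed)
  keep <- !isHypothetical(protocol)
  b <- bValues(protocol)[keep]
  U <- gradientDirections(protocol)[, keep, drop = FALSE]
  lower <- c(0, 1e-5, 0, 0, -pi / 2, 0, -pi / 2, 0)
  upper <- c(2 * max(signal), 1e-2, 1, 1, pi / 2, 2 * pi, pi / 2, 2 * pi)
  if (!is.null(nuisance)) {
    dw <- b > 0
    Rb <- nuisance@rotation %*% U
    phis <- .initAzimuths(signal[dw], Rb[1L, dw], Rb[2L, dw],
                          b[dw] * nuisance@d, nuisance@S0, nuisance@F)
    t1 <- drop(t(nuisance@rotation) %*% c(cos(phis[1L]), sin(phis[1L]), 0))
    t2 <- drop(t(nuisance@rotation) %*% c(cos(phis[2L]), sin(phis[2L]), 0))
    a1 <- anglesFromDirection(t1, degrees = FALSE)
    a2 <- anglesFromDirection(t2, degrees = FALSE)
    init <- c(nuisance@S0, nuisance@d, nuisance@F / 2, nuisance@F / 2,
              a1$theta, a1$phi, a2$theta, a2$phi, 0.05 * nuisance@S0)
  } else {
    S00 <- if (any(b == 0)) mean(signal[b == 0]) else max(signal)
    init <- c(S00, 7e-4, 0.3, 0.3, 0, pi / 4, 0, 3 * pi / 4, 0.05 * S00)
  }
  eps0 <- c(0.02 * init[1L], 2e-5, 0.05, 0.05, 0.1, 0.1, 0.1, 0.1)
  stepFun <- function(ini, eps, nIter, batchOffset)
    .cpp_run_full(signal, U, b, ini, eps, lower, upper, as.integer(nIter),
                  config$adaptInterval, config$targetAccept,
                  .precType(config), config$priorShape, config$priorRate,
                  as.integer(batchOffset))
  out <- .runSegmented(stepFun, init, eps0, config)
  new("MCMCChain", samples = out$samples,
      parnames = c("S0", "d", "f1", "f2", "theta1", "phi1", "theta2", "phi2",
                   "sigma"),
      proposalSd = out$eps, acceptance = out$accept,
      model = "full", config = unclass(config), stoppedAt = out$stoppedAt)
}

# thinned post-burn-in sample matrix
.keptSamples <- function(chain, burnInFraction = NULL, thin = NULL) {
  cfg <- chain@config
  if (is.null(burnInFraction)) burnInFraction <- cfg$burnInFraction
  if (is.null(thin)) thin <- cfg$thin
  n <- nrow(chain@samples)
  from <- floor(n * burnInFraction) + 1L
  if (from >= n) stop("chain shorter than the burn-in period")
  idx <- seq(from, n, by = thin)
  chain@samples[idx, , drop = FALSE]
}

# mean-dyadic-tensor principal axis of a 3 x m set of axes: the standard
# wrap-safe posterior summary direction for fiber orientations
.dyadicMeanAxis <- function(T) {
  E <- tcrossprod(T) / ncol(T)
  v <- eigen(E, symmetric = TRUE)$vectors[, 1L]
  v / sqrt(sum(v^2))
}

# axial summaries of a direction sample: dyadic axis, wrap-aware median/sd
# of elevation and azimuth (axes canonicalized to azimuth in [0, 180))
.directionSummary <- function(T) {
  axis <- .dyadicMeanAxis(T)
  flip <- colSums(T * axis) < 0
  T[, flip] <- -T[, flip]
  ang <- anglesFromDirection(T)
  aAxis <- anglesFromDirection(axis)
  devPhi <- ((ang$phi - aAxis$phi + 90) %% 180) - 90
  phiMed <- (aAxis$phi + median(devPhi)) %% 360
  thMed <- median(ang$theta)
  if (phiMed >= 180) { phiMed <- phiMed - 180; thMed <- -thMed; axis <- -axis
                       ang$theta <- -ang$theta }
  list(axis = if (axis[3L] < 0 && abs(axis[3L]) > 1e-12) axis else axis,
       thetaMedian = thMed, thetaSd = sd(ang$theta),
       phiMedian = phiMed, phiSd = sd(devPhi))
}

#' Summarize a posterior chain
#'
#' Discards the burn-in, thins, and reports posterior medians and standard
#' deviations of every parameter.  For the simplified model f2 is derived as
#' F - f1 and the rotated-frame azimuths (theta' = 0, phi'_k) are re-rotated
#' back into original-frame fiber axes through the transpose of the
#' longitudinal-axis rotation.  Fiber axes are summarized by the principal
#' axis of the mean dyadic tensor (wrap-safe under the antipodal symmetry)
#' with azimuths canonicalized to [0, 180).
#'
#' @param chain an \code{\link{MCMCChain}}.
#' @param nuisance the \code{\link{NuisanceEstimates}} used for the fit
#'   (required for simplified chains).
#' @param burnInFraction,thin override the chain's configuration.
#' @return list with \code{summary} (data.frame: parameter, median, sd),
#'   \code{directions} (3 x 2 matrix of summary fiber axes, original frame)
#'   and \code{fractions} (posterior-median volume fractions).
#' @export
summarizePosterior <- function(chain, nuisance = NULL, burnInFraction = NULL,
                               thin = NULL) {
  S <- .keptSamples(chain, burnInFraction, thin)
  colnames(S) <- chain@parnames
  if (chain@model == "simplified") {
    if (is.null(nuisance)) stop("simplified chains need the nuisance estimates")
    Rt <- t(nuisance@rotation)
    # the likelihood is invariant under the label exchange
    # (f1, phi'1, phi'2) -> (F - f1, phi'2, phi'1); canonicalize each draw to
    # phi'1 <= phi'2 so marginal summaries are not contaminated by
    # label switching
    swap <- S[, "phi1p"] > S[, "phi2p"]
    if (any(swap)) {
      tmp <- S[swap, "phi1p"]
      S[swap, "phi1p"] <- S[swap, "phi2p"]
      S[swap, "phi2p"] <- tmp
      S[swap, "f1"] <- nuisance@F - S[swap, "f1"]
    }
    f1 <- S[, "f1"]; f2 <- nuisance@F - f1
    T1 <- Rt %*% rbind(cos(S[, "phi1p"]), sin(S[, "phi1p"]), 0)
    T2 <- Rt %*% rbind(cos(S[, "phi2p"]), sin(S[, "phi2p"]), 0)
    d1 <- .directionSummary(T1); d2 <- .directionSummary(T2)
    summary <- data.frame(
      parameter = c("f1", "f2", "theta1", "phi1", "theta2", "phi2", "sigma"),
      median = c(median(f1), median(f2), d1$thetaMedian, d1$phiMedian,
                 d2$thetaMedian, d2$phiMedian, median(S[, "sigma"])),
      sd = c(sd(f1), sd(f2), d1$thetaSd, d1$phiSd, d2$thetaSd, d2$phiSd,
             sd(S[, "sigma"])))
    list(summary = summary, directions = cbind(d1$axis, d2$axis),
         fractions = c(median(f1), median(f2)), samples = S)
  } else {
    T1 <- directionFromAngles(S[, "theta1"], S[, "phi1"], degrees = FALSE)
    T2 <- directionFromAngles(S[, "theta2"], S[, "phi2"], degrees = FALSE)
    # canonicalize the exchangeable fiber labels per draw: order by the
    # axial azimuth of the stick (azimuth mod 180 degrees)
    az1 <- anglesFromDirection(T1)$phi %% 180
    az2 <- anglesFromDirection(T2)$phi %% 180
    swap <- az1 > az2
    if (any(swap)) {
      tmp <- T1[, swap]; T1[, swap] <- T2[, swap]; T2[, swap] <- tmp
      tmp <- S[swap, "f1"]; S[swap, "f1"] <- S[swap, "f2"]; S[swap, "f2"] <- tmp
    }
    d1 <- .directionSummary(T1); d2 <- .directionSummary(T2)
    summary <- data.frame(
      parameter = c("S0", "d", "f1", "f2", "theta1", "phi1", "theta2", "phi2",
                    "sigma"),
      median = c(median(S[, "S0"]), median(S[, "d"]), median(S[, "f1"]),
                 median(S[, "f2"]), d1$thetaMedian, d1$phiMedian,
                 d2$thetaMedian, d2$phiMedian, median(S[, "sigma"])),
      sd = c(sd(S[, "S0"]), sd(S[, "d"]), sd(S[, "f1"]), sd(S[, "f2"]),
             d1$thetaSd, d1$phiSd, d2$thetaSd, d2$phiSd, sd(S[, "sigma"])))
    list(summary = summary, directions = cbind(d1$axis, d2$axis),
         fractions = c(median(S[, "f1"]), median(S[, "f2"])), samples = S)
  }
}
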