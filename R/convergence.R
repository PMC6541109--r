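# Voxel-level convergence control: Geweke diagnostic, dynamic stopping, and
# the 1- vs 2-fiber screen on the sampled chain.

#' Dynamic stopping rule parameters
#'
#' @param checkInterval iterations between convergence checks (default 5000).
#' @param zThreshold absolute Geweke z below which a parameter is considered
#'   stationary (default 2).
#' @param windowA early-window fraction (default 0.1).
#' @param windowB late-window fraction (default 0.5).
#' @param minIterations minimum chain length before stopping is allowed
#'   (default 10000).
#' @return a list of class "stoppingRule".
#' @export
stoppingRule <- function(checkInterval = 5000L, zThreshold = 2,
                         windowA = 0.1, windowB = 0.5, minIterations = 10000L) {
  if (windowA + windowB > 1) stop("windowA + windowB must be <= 1")
  if (zThreshold <= 0) stop("zThreshold must be positive")
  structure(list(checkInterval = as.integer(checkInterval),
                 zThreshold = zThreshold, windowA = windowA, windowB = windowB,
                 minIterations = as.integer(minIterations)),
            class = "stoppingRule")
}

# spectral density at frequency zero via a Bartlett lag window over the
# first 4 percent of lags; robust for segments of a few hundred draws and up
.spectrum0 <- function(x) {
  n <- length(x)
  v <- var(x)
  if (v == 0) return(0)
  K <- max(1L, floor(0.04 * n))
  rho <- acf(x, lag.max = K, plot = FALSE, demean = TRUE)$acf[-1L]
  w <- 1 - seq_len(K) / (K + 1)
  max(v * (1 + 2 * sum(w * rho)), 1e-12 * v)
}

#' Geweke convergence z-score
#'
#' Compares the mean of an early window against the mean of a late window,
#' standardized by spectral-density-at-zero variance estimates:
#' z = (mean_A - mean_B) / sqrt(sV_A/n_A + sV_B/n_B).  A stationary chain
#' gives |z| of order 1; a trending chain gives large |z|.
#'
#' @param x numeric chain segment (length >= 100).
#' @param windowA early fraction (default 0.1).
#' @param windowB late fraction (default 0.5).
#' @return the z score; a constant (zero-variance) segment returns 0, a
#'   constant chain being trivially converged.
#' @export
gewekeZ <- function(x, windowA = 0.1, windowB = 0.5) {
  n <- length(x)
  if (n < 100L) stop("segment too short for the Geweke diagnostic")
  a <- x[seq_len(floor(windowA * n))]
  b <- x[seq.int(n - floor(windowB * n) + 1L, n)]
  va <- .spectrum0(a) / length(a)
  vb <- .spectrum0(b) / length(b)
  if (va + vb == 0) return(0)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

#' Dynamic stopping decision
#'
#' Stops when every sampled parameter's Geweke z is below the threshold in
#' magnitude, once the minimum iteration count has elapsed.
#'
#' @param samples iterations x parameters matrix (raw chains so far).
#' @param rule a \code{\link{stoppingRule}}.
#' @param iteration current iteration count (default nrow(samples)).
#' @return list with \code{stop} (logical), \code{iteration}, and the
#'   per-parameter \code{z} scores.
#' @export
shouldStop <- function(samples, rule = stoppingRule(), iteration = nrow(samples)) {
  if (iteration < rule$minIterations)
    return(list(stop = FALSE, iteration = iteration, z = NULL))
  z <- apply(samples, 2L, gewekeZ, windowA = rule$windowA, windowB = rule$windowB)
  list(stop = all(abs(z) < rule$zThreshold), iteration = iteration, z = z)
}

#' Screen a two-fiber chain for one-fiber data
#'
#' Fitting the two-fiber simplified model to one-fiber data over-fits: the
#' surplus stick either collapses to a negligible fraction or lands on top
#' of the real one.  The screen declares one fiber when the posterior median
#' of the smaller fraction min(f1, F - f1) falls below \code{fMin}, or when
#' the posterior median of the (axially wrapped) inter-fiber angle
#' |phi'1 - phi'2| falls below \code{angleMin} degrees.
#'
#' @param chain a simplified-model \code{\link{MCMCChain}}.
#' @param nuisance the \code{\link{NuisanceEstimates}} used for the fit.
#' @param fMin smallest credible fraction (default 0.2).  Calibrated on the
#'   one-fiber benchmark voxel at SNR 20: clipping of the total stick
#'   fraction at 1 leaks the ~0.1 isotropic fraction into the surplus
#'   stick, and partial-overlap fits spread it further, so the screen sits
#'   well above that leakage level.
#' @param angleMin smallest credible separation in degrees (default 45).
#'   Crossings tighter than this are at the angular resolution limit of a
#'   64-direction single-shell acquisition at SNR 20 and are indistinguishable
#'   from an over-fitted single fiber.
#' @return 1L or 2L (fiber count).
#' @export
classifyFiberCount <- function(chain, nuisance, fMin = 0.2, angleMin = 45) {
  if (nuisance@F <= 0)
    stop("total stick fraction is zero: isotropic voxel, nothing to classify")
  S <- .keptSamples(chain)
  colnames(S) <- chain@parnames
  fSmall <- pmin(S[, "f1"], nuisance@F - S[, "f1"])
  dphi <- abs(S[, "phi1p"] - S[, "phi2p"]) * 180 / pi
  dphi <- pmin(dphi, 180 - dphi)
  if (median(fSmall) < fMin || median(dphi) < angleMin) 1L else 2L
}
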