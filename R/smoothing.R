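# von-Mises kernel smoothing of the DW signal over gradient directions, and
# the smoothing-based estimators of the longitudinal axis and max(S).

#' von-Mises kernel weight
#'
#' Density of the von-Mises distribution at angular distance x:
#' exp(kappa cos x) / (2 pi I0(kappa)).  Only relative weights matter when
#' smoothing (the normalization cancels in the weighted average); for large
#' kappa the unnormalized exponent is used internally with the maximum
#' subtracted before exponentiation to avoid overflow.
#'
#' @param x angular distance(s) in radians.
#' @param kappa concentration parameter, >= 0.
#' @return density value(s).
#' @export
vonMisesWeight <- function(x, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  exp(kappa * cos(x)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE) * exp(kappa))
}

# weight matrix: rows = targets, cols = observed; axial angular distance
.vonMisesWeights <- function(targets, observed, kappa) {
  x <- acos(pmin(abs(crossprod(targets, observed)), 1))
  e <- kappa * cos(x)
  e <- e - apply(e, 1L, max)
  W <- exp(e)
  W / rowSums(W)
}

#' Smooth a DW signal over the sphere with a von-Mises kernel
#'
#' Each smoothed value is the convex combination of the observed b > 0
#' intensities, weighted by the von-Mises density of the *axial* angular
#' distance (arccos |r_i . r_j|) between target and observed directions.
#' The axial metric respects the antipodal symmetry of the DW signal; a
#' polar metric would mix hemispheres incoherently at small kappa.
#'
#' @param signal observed signal vector (non-hypothetical protocol entries).
#' @param protocol a \code{\link{DWIProtocol}}.
#' @param targets 3 x m matrix of evaluation directions; default: every
#'   direction in the protocol (observed DW plus hypothetical).
#' @param kappa concentration of the smoothing kernel.
#' @return numeric vector of smoothed values at the targets, each within
#'   the range of the observed values.
#' @export
smoothSignal <- function(signal, protocol, targets = NULL, kappa) {
  keep <- !isHypothetical(protocol)
  if (length(signal) != sum(keep))
    stop("signal length must match the non-hypothetical protocol entries")
  dw <- bValues(protocol)[keep] > 0
  obs <- gradientDirections(protocol)[, keep, drop = FALSE][, dw, drop = FALSE]
  if (ncol(obs) == 0L) stop("no diffusion-weighted observations to smooth")
  y <- signal[dw]
  if (is.null(targets)) {
    idx <- bValues(protocol) > 0
    targets <- gradientDirections(protocol)[, idx, drop = FALSE]
  }
  targets <- as.matrix(targets)
  drop(.vonMisesWeights(targets, obs, kappa) %*% y)
}

# local continuous maximization of the smoothed field around a starting
# direction, parameterized on the tangent plane; the von-Mises smoother is
# defined for arbitrary targets, so the maximum need not sit on the grid
.refineSmoothedArgmax <- function(signal, protocol, start, kappa) {
  e1 <- if (abs(start[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * start) * start
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(start[2L] * e1[3L] - start[3L] * e1[2L],
          start[3L] * e1[1L] - start[1L] * e1[3L],
          start[1L] * e1[2L] - start[2L] * e1[1L])
  obj <- function(p) {
    u <- start + p[1L] * e1 + p[2L] * e2
    u <- u / sqrt(sum(u^2))
    -smoothSignal(signal, protocol, targets = matrix(u, 3L, 1L), kappa = kappa)
  }
  o <- stats::optim(c(0, 0), obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 500L))
  u <- start + o$par[1L] * e1 + o$par[2L] * e2
  list(axis = u / sqrt(sum(u^2)), value = -o$value)
}

#' Estimate the longitudinal axis from the smoothed signal
#'
#' The longitudinal axis (common perpendicular of the two fibers) carries
#' the maximum DW signal.  It is estimated as the direction -- observed or
#' hypothetical -- maximizing the kappa2-smoothed signal.  A very diffuse
#' kernel (default kappa2 = 0.1) makes the argmax respond to the global
#' shape of the signal surface rather than single noisy measurements.
#'
#' @param signal observed signal vector.
#' @param protocol a \code{\link{DWIProtocol}}.
#' @param kappa2 concentration for the axis search (default 0.1).
#' @param useHypothetical search hypothetical directions too (default TRUE).
#' @param refine continue from the best grid direction with a local
#'   continuous maximization of the smoothed field (default TRUE); FALSE
#'   returns the discrete grid argmax, whose accuracy is limited by the
#'   angular spacing of the direction set.
#' @return unit 3-vector (z >= 0); grid ties broken by lowest protocol index.
#' @export
estimateLongitudinalAxis <- function(signal, protocol, kappa2 = 0.1,
                                     useHypothetical = TRUE, refine = TRUE) {
  idx <- bValues(protocol) > 0
  if (!useHypothetical) idx <- idx & !isHypothetical(protocol)
  targets <- gradientDirections(protocol)[, idx, drop = FALSE]
  sm <- smoothSignal(signal, protocol, targets = targets, kappa = kappa2)
  # lowest-index tie-break, robust to float jitter in the weight sums
  best <- which(sm >= max(sm) - 1e-9 * (abs(max(sm)) + 1))[1L]
  axis <- targets[, best]
  if (refine)
    axis <- .refineSmoothedArgmax(signal, protocol, axis, kappa2)$axis
  if (axis[3L] < 0) axis <- -axis
  unname(axis)
}

#' Estimate the maximum DW signal magnitude from the smoothed signal
#'
#' max(S) enters the smoothed-maximum identity used to solve for the
#' diffusivity and total stick fraction; smoothing (default kappa = 50,
#' a good empirical range being 35-70) suppresses the upward bias a raw
#' noisy maximum would carry.
#'
#' @param signal observed signal vector.
#' @param protocol a \code{\link{DWIProtocol}}.
#' @param kappa concentration for the max-signal search (default 50); a
#'   warning is issued outside [1, 200].
#' @param useHypothetical search hypothetical directions too (default TRUE).
#' @param refine continue from the best grid direction with a local
#'   continuous maximization (default FALSE: the discrete smoothed maximum
#'   is the estimator whose bias the kappa guidance is calibrated around;
#'   see the methods vignette).
#' @return scalar estimate of max(S).
#' @export
estimateMaxSignal <- function(signal, protocol, kappa = 50,
                              useHypothetical = TRUE, refine = FALSE) {
  if (kappa < 1 || kappa > 200)
    warning("kappa = ", kappa, " is outside the recommended range [1, 200]")
  idx <- bValues(protocol) > 0
  if (!useHypothetical) idx <- idx & !isHypothetical(protocol)
  targets <- gradientDirections(protocol)[, idx, drop = FALSE]
  sm <- smoothSignal(signal, protocol, targets = targets, kappa = kappa)
  if (!refine) return(max(sm))
  best <- targets[, which.max(sm)]
  .refineSmoothedArgmax(signal, protocol, best, kappa)$value
}
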