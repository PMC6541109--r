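#' @import methods
#' @importFrom stats median sd rnorm runif rgamma pnorm quantile var acf IQR uniroot setNames
#' @importFrom utils head modifyList
#' @importFrom Rcpp evalCpp
#' @useDynLib ballstick, .registration = TRUE
NULL

#' DWIProtocol: a single-shell diffusion acquisition scheme
#'
#' Holds the gradient unit vectors and b-values of a diffusion-weighted
#' acquisition, plus optional *hypothetical* directions.  Hypothetical
#' directions carry no measured signal; they only serve as extra evaluation
#' points when searching for the maximum of the kernel-smoothed signal, which
#' improves the angular resolution of the longitudinal-axis estimate beyond
#' the granularity of the acquired scheme.
#'
#' Directions follow the elevation convention: \code{theta} is the angle from
#' the XY-plane in [-90, 90] degrees (so theta = 90 is the +Z pole, *not*
#' colatitude) and \code{phi} is the azimuth from the X-axis in [0, 360).
#'
#' @slot bvecs 3 x n matrix of unit gradient directions (columns); b = 0
#'   entries may be the zero vector.
#' @slot bvals numeric vector of diffusion weightings in s/mm^2.
#' @slot hypothetical logical vector flagging smoothing-only directions.
#' @export
setClass("DWIProtocol",
  representation(bvecs = "matrix", bvals = "numeric", hypothetical = "logical"))

setValidity("DWIProtocol", function(object) {
  n <- length(object@bvals)
  if (!is.numeric(object@bvecs) || nrow(object@bvecs) != 3L || ncol(object@bvecs) != n)
    return("bvecs must be a 3 x length(bvals) numeric matrix")
  if (length(object@hypothetical) != n)
    return("hypothetical flag must match the number of acquisitions")
  if (any(object@bvals < 0)) return("b-values must be non-negative")
  if (any(object@hypothetical & object@bvals == 0))
    return("hypothetical entries must be diffusion-weighted (b > 0)")
  nrm <- sqrt(colSums(object@bvecs^2))
  bad <- object@bvals > 0 & abs(nrm - 1) > 1e-6
  if (any(bad)) return("directions of b > 0 acquisitions must be unit vectors")
  TRUE
})

#' VoxelModel: ground-truth Ball-and-Stick parameters for one voxel
#'
#' The Ball-and-Stick model splits the voxel signal into an isotropic "ball"
#' compartment with volume fraction 1 - sum(f) and L anisotropic "stick"
#' compartments, each with fraction f_k and axis t_k.  Gaussian i.i.d. noise
#' of standard deviation \code{sigma} is added per acquisition.
#'
#' @slot S0 baseline (b = 0) signal intensity, arbitrary units.
#' @slot d diffusivity in mm^2/s.
#' @slot fractions per-stick volume fractions, sum <= 1.
#' @slot orientations 3 x L matrix of unit stick axes.
#' @slot sigma noise standard deviation (same units as S0).
#' @export
setClass("VoxelModel",
  representation(S0 = "numeric", d = "numeric", fractions = "numeric",
                 orientations = "matrix", sigma = "numeric"))

setValidity("VoxelModel", function(object) {
  if (length(object@S0) != 1L || object@S0 <= 0) return("S0 must be a positive scalar")
  if (length(object@d) != 1L || object@d <= 0) return("d must be a positive scalar")
  if (length(object@sigma) != 1L || object@sigma < 0) return("sigma must be >= 0")
  L <- length(object@fractions)
  if (any(object@fractions < 0) || any(object@fractions > 1))
    return("fractions must lie in [0, 1]")
  if (sum(object@fractions) > 1 + 1e-12)
    return("stick fractions must sum to at most 1")
  if (L > 0L) {
    if (nrow(object@orientations) != 3L || ncol(object@orientations) != L)
      return("orientations must be a 3 x L matrix")
    if (any(abs(sqrt(colSums(object@orientations^2)) - 1) > 1e-8))
      return("stick orientations must be unit vectors")
  }
  TRUE
})

#' NuisanceEstimates: stage-one closed-form estimates
#'
#' Output of the non-MCMC estimation stage: baseline signal, diffusivity and
#' total stick fraction solved from the spherical-mean and smoothed-maximum
#' equations, plus the estimated longitudinal axis (the common perpendicular
#' of the two fibers, where the DW signal peaks) and the rotation taking that
#' axis onto +Z.
#'
#' @slot S0 estimated baseline intensity.
#' @slot d estimated diffusivity (mm^2/s).
#' @slot F estimated total stick fraction, in [0, 1].
#' @slot axis estimated longitudinal axis (unit 3-vector).
#' @slot rotation 3 x 3 rotation with rotation %*% axis = (0, 0, 1).
#' @export
setClass("NuisanceEstimates",
  representation(S0 = "numeric", d = "numeric", F = "numeric",
                 axis = "numeric", rotation = "matrix"))

setValidity("NuisanceEstimates", function(object) {
  if (object@d <= 0) return("d must be positive")
  if (object@F < 0 || object@F > 1) return("F must lie in [0, 1]")
  if (length(object@axis) != 3L || abs(sqrt(sum(object@axis^2)) - 1) > 1e-8)
    return("axis must be a unit 3-vector")
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(R %*% t(R) - diag(3))) > 1e-8) return("rotation must be orthonormal")
  if (max(abs(as.numeric(R %*% object@axis) - c(0, 0, 1))) > 1e-8)
    return("rotation must map the axis onto (0, 0, 1)")
  TRUE
})

#' MCMCChain: sampled parameter chains from an adaptive sampler
#'
#' @slot samples iterations x parameters matrix of raw (unthinned) draws.
#' @slot parnames parameter names, column order of \code{samples}.
#' @slot proposalSd final per-parameter random-walk proposal scales.
#' @slot acceptance overall per-parameter acceptance rates.
#' @slot model "simplified" or "full".
#' @slot config the \code{\link{mcmcConfig}} list used.
#' @slot stoppedAt iteration at which the dynamic stopping rule fired
#'   (equal to nrow(samples); NA_integer_ when stopping was disabled).
#' @export
setClass("MCMCChain",
  representation(samples = "matrix", parnames = "character",
                 proposalSd = "numeric", acceptance = "numeric",
                 model = "character", config = "list", stoppedAt = "integer"))

setValidity("MCMCChain", function(object) {
  if (ncol(object@samples) != length(object@parnames))
    return("parnames must match the sample columns")
  if (any(object@proposalSd <= 0)) return("proposal scales must be positive")
  TRUE
})

setMethod("show", "DWIProtocol", function(object) {
  nb0 <- sum(object@bvals == 0)
  nh <- sum(object@hypothetical)
  cat("DWIProtocol:", length(object@bvals) - nh - nb0, "DW directions,",
      nb0, "b=0,", nh, "hypothetical\n")
  cat("  b-values (s/mm^2):", paste(unique(object@bvals), collapse = ", "), "\n")
})

setMethod("show", "VoxelModel", function(object) {
  cat("VoxelModel: S0 =", object@S0, ", d =", signif(object@d, 4),
      "mm^2/s, sigma =", object@sigma, "\n")
  L <- length(object@fractions)
  if (L == 0L) cat("  isotropic (no sticks)\n")
  for (k in seq_len(L)) {
    ang <- anglesFromDirection(object@orientations[, k])
    cat(sprintf("  stick %d: f = %.3f, theta = %.1f, phi = %.1f\n",
                k, object@fractions[k], ang$theta, ang$phi))
  }
})

setMethod("show", "NuisanceEstimates", function(object) {
  ang <- anglesFromDirection(object@axis)
  cat(sprintf("NuisanceEstimates: S0 = %.2f, d = %.4g mm^2/s, F = %.3f\n",
              object@S0, object@d, object@F))
  cat(sprintf("  longitudinal axis: theta = %.1f, phi = %.1f\n", ang$theta, ang$phi))
})

setMethod("show", "MCMCChain", function(object) {
  cat(sprintf("MCMCChain (%s model): %d iterations x %d parameters\n",
              object@model, nrow(object@samples), ncol(object@samples)))
  cat("  acceptance:", paste(sprintf("%s %.2f", object@parnames[seq_along(object@acceptance)],
                                     object@acceptance), collapse = ", "), "\n")
  if (!is.na(object@stoppedAt)) cat("  stopped at iteration", object@stoppedAt, "\n")
})

# ---- accessors -------------------------------------------------------------

#' Protocol accessors
#'
#' @param object a \code{DWIProtocol}.
#' @return \code{bValues} the b-value vector; \code{gradientDirections} the
#'   3 x n direction matrix; \code{isHypothetical} the smoothing-only flag;
#'   \code{nAcquisitions} the number of entries carrying measured signal
#'   (hypothetical directions excluded).
#' @export
bValues <- function(object) object@bvals

#' @rdname bValues
#' @export
gradientDirections <- function(object) object@bvecs

#' @rdname bValues
#' @export
isHypothetical <- function(object) object@hypothetical

#' @rdname bValues
#' @export
nAcquisitions <- function(object) sum(!object@hypothetical)

#' Chain accessors
#'
#' @param object an \code{MCMCChain}.
#' @return \code{chainSamples} the raw iterations x parameters matrix;
#'   \code{acceptanceRates} the per-parameter Metropolis acceptance rates.
#' @export
chainSamples <- function(object) {
  s <- object@samples
  colnames(s) <- object@parnames
  s
}

#' @rdname chainSamples
#' @export
acceptanceRates <- function(object) setNames(object@acceptance,
                                             object@parnames[seq_along(object@acceptance)])

#' Construct a DWIProtocol
#'
#' @param bvecs 3 x n matrix of directions (columns); non-unit columns with
#'   b > 0 are renormalized.
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param hypothetical logical flag per entry (default all observed).
#' @return a \code{\link{DWIProtocol}}.
#' @export
dwiProtocol <- function(bvecs, bvals, hypothetical = rep(FALSE, length(bvals))) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  nrm <- sqrt(colSums(bvecs^2))
  scale <- ifelse(bvals > 0 & nrm > 0, 1 / nrm, 1)
  bvecs <- sweep(bvecs, 2L, scale, "*")
  new("DWIProtocol", bvecs = bvecs, bvals = as.numeric(bvals),
      hypothetical = as.logical(hypothetical))
}

#' Construct a VoxelModel
#'
#' @param S0 baseline intensity.
#' @param d diffusivity (mm^2/s).
#' @param fractions per-stick volume fractions (may be empty).
#' @param theta,phi per-stick elevation/azimuth in degrees, or
#' @param orientations a 3 x L matrix of unit axes (overrides angles).
#' @param sigma Gaussian noise standard deviation.
#' @return a \code{\link{VoxelModel}}.
#' @export
voxelModel <- function(S0, d, fractions = numeric(0), theta = NULL, phi = NULL,
                       orientations = NULL, sigma = 0) {
  L <- length(fractions)
  if (is.null(orientations)) {
    if (L > 0L && (length(theta) != L || length(phi) != L))
      stop("theta and phi must have one entry per stick")
    orientations <- if (L > 0L) directionFromAngles(theta, phi) else
      matrix(numeric(0), 3L, 0L)
  }
  new("VoxelModel", S0 = S0, d = d, fractions = as.numeric(fractions),
      orientations = as.matrix(orientations), sigma = sigma)
}
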