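# Ball-and-Stick signal synthesis and the synthetic-voxel scenario registry.

#' Single-stick attenuation factor
#'
#' The stick compartment attenuates the signal by exp(-b d cos^2(Delta)),
#' where Delta is the angle between the gradient r and the stick axis t;
#' cos^2(Delta) = (r . t)^2 is the quadratic form r' R A R' r with
#' A = diag(1, 0, 0) evaluated in the stick frame.
#'
#' @param r gradient unit 3-vector (or 3 x n matrix).
#' @param t stick unit 3-vector.
#' @param b diffusion weighting (s/mm^2).
#' @param d diffusivity (mm^2/s).
#' @return attenuation factor(s) in (0, 1].
#' @export
stickAttenuation <- function(r, t, b, d) {
  if (b < 0 || d < 0) stop("b and d must be non-negative")
  r <- as.matrix(r)
  exp(-b * d * colSums(r * as.numeric(t))^2)
}

#' Predict the noiseless Ball-and-Stick signal
#'
#' S_i = S0 [ (1 - sum f_k) exp(-b_i d) + sum_k f_k exp(-b_i d (r_i . t_k)^2) ].
#' Entries with b = 0 equal S0 exactly.  Hypothetical protocol entries are
#' skipped: no signal is ever predicted (or measured) for them.
#'
#' @param model a \code{\link{VoxelModel}}.
#' @param protocol a \code{\link{DWIProtocol}}.
#' @return numeric vector over the non-hypothetical protocol entries.
#' @export
predictSignal <- function(model, protocol) {
  if (sum(model@fractions) > 1 + 1e-12) stop("stick fractions must sum to at most 1")
  keep <- !isHypothetical(protocol)
  b <- bValues(protocol)[keep]
  U <- gradientDirections(protocol)[, keep, drop = FALSE]
  F <- sum(model@fractions)
  s <- (1 - F) * exp(-b * model@d)
  for (k in seq_along(model@fractions)) {
    c2 <- colSums(U * model@orientations[, k])^2
    s <- s + model@fractions[k] * exp(-b * model@d * c2)
  }
  unname(model@S0 * s)
}

#' Predict the simplified (rotated-frame) two-fiber signal
#'
#' The simplified model is evaluated in the rotated frame in which the
#' crossing-fiber plane is the XY-plane, so each fiber axis reduces to one
#' azimuth: S_i = S0h [ (1 - F) exp(-b dh) + f1 exp(-b dh (r'x cos(p1) +
#' r'y sin(p1))^2) + (F - f1) exp(-b dh (r'x cos(p2) + r'y sin(p2))^2) ],
#' with f2 = F - f1 by construction.
#'
#' @param f1 first-fiber volume fraction, in [0, F].
#' @param phi1p,phi2p rotated-frame fiber azimuths in radians, [0, pi).
#' @param nuisance a \code{\link{NuisanceEstimates}} supplying S0h, dh, F.
#' @param rotatedBvecs 3 x n matrix of gradients already mapped through the
#'   rotation (columns aligned with \code{bvals}).
#' @param bvals b-values for those columns.
#' @return numeric signal vector.
#' @export
predictSignalSimplified <- function(f1, phi1p, phi2p, nuisance, rotatedBvecs, bvals) {
  F <- nuisance@F
  if (f1 < -1e-12 || f1 > F + 1e-12) stop("f1 must lie in [0, F]")
  rx <- rotatedBvecs[1L, ]; ry <- rotatedBvecs[2L, ]
  bd <- bvals * nuisance@d
  s <- (1 - F) * exp(-bd) +
    f1 * exp(-bd * (rx * cos(phi1p) + ry * sin(phi1p))^2) +
    (F - f1) * exp(-bd * (rx * cos(phi2p) + ry * sin(phi2p))^2)
  out <- nuisance@S0 * s
  out[bvals == 0] <- nuisance@S0
  unname(out)
}

#' Add i.i.d. Gaussian noise to a signal
#'
#' @param signal numeric vector.
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional integer seed (draws come from the current RNG stream
#'   when NULL).
#' @return noisy signal, deterministic given the seed.
#' @export
addNoise <- function(signal, sigma, seed = NULL) {
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(signal)
  if (!is.null(seed)) withr_seed(seed, signal + rnorm(length(signal), 0, sigma))
  else signal + rnorm(length(signal), 0, sigma)
}

# fixed gradient tables are expensive to regenerate; memoize per size
.schemeCache <- new.env(parent = emptyenv())

.fixedScheme <- function(nGradients, nB0 = 0L, b = 1500, hypothetical = TRUE) {
  key <- paste0("n", nGradients, "b0_", nB0, "h", hypothetical)
  if (!is.null(.schemeCache[[key]])) return(.schemeCache[[key]])
  U <- generateUniformDirections(nGradients)
  bvecs <- cbind(matrix(0, 3L, nB0), U)
  bvals <- c(rep(0, nB0), rep(b, nGradients))
  prot <- dwiProtocol(bvecs, bvals)
  if (hypothetical) prot <- addHypotheticalDirections(prot)
  .schemeCache[[key]] <- prot
  prot
}

.scenarioTable <- function() list(
  # default two-fiber crossing: S0 = 400, b = 1500 s/mm^2, d = 1/1500 mm^2/s,
  # f = (0.4, 0.5), fibers in the XY-plane at 60 and 120 degrees azimuth,
  # SNR 20 (sigma = 20)
  "paper-default-64"  = list(n = 64L, f = c(0.4, 0.5), theta = c(0, 0),
                             phi = c(60, 120), sigma = 20),
  "paper-default-128" = list(n = 128L, f = c(0.4, 0.5), theta = c(0, 0),
                             phi = c(60, 120), sigma = 20),
  # angular-separation variants, fibers symmetric about 90 degrees azimuth
  "separation-30-64"  = list(n = 64L, f = c(0.4, 0.5), theta = c(0, 0),
                             phi = 90 + c(-15, 15), sigma = 20),
  "separation-40-64"  = list(n = 64L, f = c(0.4, 0.5), theta = c(0, 0),
                             phi = 90 + c(-20, 20), sigma = 20),
  "separation-40-128" = list(n = 128L, f = c(0.4, 0.5), theta = c(0, 0),
                             phi = 90 + c(-20, 20), sigma = 20),
  "separation-50-64"  = list(n = 64L, f = c(0.4, 0.5), theta = c(0, 0),
                             phi = 90 + c(-25, 25), sigma = 20),
  "separation-60-64"  = list(n = 64L, f = c(0.4, 0.5), theta = c(0, 0),
                             phi = 90 + c(-30, 30), sigma = 20),
  "separation-90-64"  = list(n = 64L, f = c(0.4, 0.5), theta = c(0, 0),
                             phi = 90 + c(-45, 45), sigma = 20),
  # one-fiber voxel for model-selection checks
  "onefiber-64"       = list(n = 64L, f = 0.9, theta = 0, phi = 60, sigma = 20),
  # three-fiber stress scenarios, sigma = 5% of S0 = 20
  "threefiber-1"      = list(n = 64L, f = c(0.3, 0.25, 0.2),
                             theta = c(0, 0, 45), phi = c(0, 90, 45), sigma = 20),
  "threefiber-2"      = list(n = 64L, f = c(0.4, 0.25, 0.1),
                             theta = c(25, 0, 0), phi = c(25, 0, 25), sigma = 20),
  "threefiber-3"      = list(n = 64L, f = c(0.25, 0.25, 0.25),
                             theta = c(0, 0, 90), phi = c(0, 90, 90), sigma = 20)
)

#' Construct a registered simulation scenario
#'
#' Returns the ground-truth voxel and acquisition scheme for one of the
#' registered benchmark scenarios.  All scenarios share S0 = 400,
#' b = 1500 s/mm^2, d = 1/1500 mm^2/s (so b d = 1) and use the package's
#' fixed evenly-distributed gradient table of the requested size with an
#' equal number of hypothetical directions appended.
#'
#' @param name scenario name; see Details.  Unknown names raise an error
#'   listing the registry.
#' @param nB0 number of b = 0 acquisitions to include (default 8).  The
#'   replication experiments additionally treat S0 as known in stage one,
#'   see \code{\link{estimateNuisance}}; the b = 0 volumes anchor the
#'   baseline for the full nine-parameter sampler, where S0 is a free
#'   parameter.
#' @param sigma override the scenario noise level (e.g. 0 for noiseless).
#' @return list with elements \code{model} (a \code{\link{VoxelModel}}) and
#'   \code{protocol} (a \code{\link{DWIProtocol}}).
#' @details Registered scenarios: two-fiber default crossing at 60/120
#'   degrees azimuth with 64 or 128 gradients ("paper-default-64/-128"),
#'   angular-separation variants ("separation-<deg>-<n>"), a one-fiber voxel
#'   ("onefiber-64") and three three-fiber stress scenarios
#'   ("threefiber-1/2/3").
#' @export
makeScenario <- function(name, nB0 = 8L, sigma = NULL) {
  tab <- .scenarioTable()
  if (!name %in% names(tab))
    stop("unknown scenario '", name, "'; known: ", paste(names(tab), collapse = ", "))
  sc <- tab[[name]]
  if (is.null(sigma)) sigma <- sc$sigma
  list(model = voxelModel(S0 = 400, d = 1 / 1500, fractions = sc$f,
                          theta = sc$theta, phi = sc$phi, sigma = sigma),
       protocol = .fixedScheme(sc$n, nB0 = nB0))
}

#' Simulate one noisy acquisition of a scenario voxel
#'
#' @param scenario output of \code{\link{makeScenario}} (or a list with
#'   \code{model} and \code{protocol}).
#' @param seed integer seed for the noise draw.
#' @return numeric signal vector over the non-hypothetical entries.
#' @export
simulateVoxel <- function(scenario, seed = NULL) {
  clean <- predictSignal(scenario$model, scenario$protocol)
  addNoise(clean, scenario$model@sigma, seed = seed)
}
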