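# Spherical geometry: direction conventions, angular metrics, the
# longitudinal-axis rotation, and gradient-scheme generation.

#' Convert elevation/azimuth angles to unit direction vectors
#'
#' Uses the elevation convention: \code{theta} measures the angle from the
#' XY-plane (theta = 90 gives +Z), \code{phi} the azimuth from the X-axis.
#' The unit vector is (cos(theta)cos(phi), cos(theta)sin(phi), sin(theta)).
#'
#' @param theta elevation angle(s).
#' @param phi azimuth angle(s).
#' @param degrees interpret angles in degrees (default) or radians.
#' @return a 3 x n matrix of unit vectors (a plain length-3 vector if n = 1).
#' @export
directionFromAngles <- function(theta, phi, degrees = TRUE) {
  if (any(!is.finite(theta)) || any(!is.finite(phi))) stop("angles must be finite")
  if (degrees) { theta <- theta * pi / 180; phi <- phi * pi / 180 }
  u <- rbind(cos(theta) * cos(phi), cos(theta) * sin(phi), sin(theta))
  if (ncol(u) == 1L) drop(u) else u
}

#' Recover elevation/azimuth from a unit direction
#'
#' Inverse of \code{\link{directionFromAngles}} up to the antipodal
#' equivalence of axes; phi is reported in [0, 360).
#'
#' @param u a 3-vector (or 3 x n matrix) of directions.
#' @param degrees return degrees (default) or radians.
#' @return list with components \code{theta} and \code{phi}.
#' @export
anglesFromDirection <- function(u, degrees = TRUE) {
  u <- as.matrix(u)
  if (nrow(u) != 3L) u <- t(u)
  nrm <- sqrt(colSums(u^2))
  if (any(nrm == 0)) stop("zero vector has no direction")
  u <- sweep(u, 2L, nrm, "/")
  theta <- asin(pmin(1, pmax(-1, u[3L, ])))
  phi <- atan2(u[2L, ], u[1L, ]) %% (2 * pi)
  if (degrees) { theta <- theta * 180 / pi; phi <- phi * 180 / pi }
  list(theta = unname(theta), phi = unname(phi))
}

#' Angular separation between two directions
#'
#' With \code{axial = TRUE} (the default) directions are treated as axes,
#' i.e. antipodally equivalent, and the angle arccos(|u . v|) lies in
#' [0, 90] degrees.  The diffusion signal depends on the gradient only
#' through cos^2 of this angle, so the axial metric is the natural one.
#'
#' @param u,v unit 3-vectors (or 3 x n matrices, compared columnwise).
#' @param axial antipodally symmetrize (default TRUE).
#' @return angle(s) in degrees.
#' @export
angularSeparation <- function(u, v, axial = TRUE) {
  u <- as.matrix(u); v <- as.matrix(v)
  nu <- sqrt(colSums(u^2)); nv <- sqrt(colSums(v^2))
  if (any(nu == 0) || any(nv == 0)) stop("zero vector has no direction")
  d <- colSums(u * v) / (nu * nv)
  if (axial) d <- abs(d)
  unname(acos(pmin(1, pmax(-1, d))) * 180 / pi)
}

#' Rotation taking a given axis onto +Z
#'
#' Builds the rotation used to map the longitudinal axis r_l (the common
#' perpendicular of the two fibers) onto the Z-axis, which puts the
#' crossing-fiber plane onto the XY-plane.  Composed of an azimuthal
#' rotation bringing r_l into the XZ-plane followed by a rotation about Y
#' through (90 - theta_l) degrees:
#' rows (sin(t)cos(p), sin(t)sin(p), -cos(t)), (-sin(p), cos(p), 0),
#' (cos(t)cos(p), cos(t)sin(p), sin(t)) for elevation t and azimuth p.
#'
#' @param axis unit 3-vector.
#' @return 3 x 3 rotation matrix R with R %*% axis = c(0, 0, 1) and the
#'   inverse mapping available as t(R).
#' @export
rotationToZ <- function(axis) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("zero vector has no direction")
  axis <- axis / nrm
  st <- axis[3L]                      # sin(theta_l)
  ct <- sqrt(max(0, 1 - st^2))        # cos(theta_l) >= 0 by convention
  if (ct < 1e-14) { cp <- 1; sp <- 0 } else { cp <- axis[1L] / ct; sp <- axis[2L] / ct }
  matrix(c(st * cp, st * sp, -ct,
           -sp,     cp,       0,
           ct * cp, ct * sp, st), nrow = 3L, byrow = TRUE)
}

# Fibonacci spiral on the upper hemisphere: deterministic starting layout
# for the repulsion solver.
.fibonacciHemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

#' Generate approximately uniform gradient directions
#'
#' Minimizes the electrostatic (Coulomb) energy of the axes together with
#' their antipodes, the standard construction for evenly distributed
#' diffusion-gradient schemes.  With \code{seed = NULL} (the default) the
#' start is a deterministic Fibonacci hemisphere layout, so the scheme plays
#' the role of a fixed published gradient table; a seed randomizes the start.
#'
#' @param n number of directions, >= 6.
#' @param seed optional integer seed for a randomized start.
#' @param iterations repulsion descent steps (default 300).
#' @return 3 x n matrix of unit axes, canonicalized to z >= 0.
#' @export
generateUniformDirections <- function(n, seed = NULL, iterations = 2000L) {
  if (n < 6L) stop("need at least 6 directions")
  if (is.null(seed)) {
    U <- .fibonacciHemisphere(n)
  } else {
    U <- withr_seed(seed, {
      z <- runif(n); phi <- runif(n, 0, 2 * pi); r <- sqrt(1 - z^2)
      rbind(r * cos(phi), r * sin(phi), z)
    })
  }
  step <- 0.3 / n
  for (it in seq_len(iterations)) {
    G <- crossprod(U)                               # n x n cosines
    dm2 <- pmax(2 - 2 * G, 1e-9); dp2 <- pmax(2 + 2 * G, 1e-9)
    Wm <- dm2^(-1.5); Wp <- dp2^(-1.5)
    diag(Wm) <- 0; diag(Wp) <- 0
    # force on axis i from axes j and their antipodes
    Fmat <- U %*% diag(colSums(Wm + Wp)) - U %*% (Wm - Wp)
    # project out the radial component; cap the step so near-coincident
    # axes separate without overshooting
    Fmat <- Fmat - U %*% diag(colSums(Fmat * U))
    disp <- step * Fmat
    m <- max(sqrt(colSums(disp^2)))
    if (m > 0.05) disp <- disp * (0.05 / m)
    U <- U + disp
    U <- sweep(U, 2L, sqrt(colSums(U^2)), "/")
  }
  neg <- U[3L, ] < 0
  U[, neg] <- -U[, neg]
  unname(U)
}

# evaluate a seeded expression without disturbing the caller's RNG stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# uniform random rotation via QR of a Gaussian matrix
.randomRotation <- function() {
  M <- matrix(rnorm(9L), 3L)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3L] <- -Q[, 3L]
  Q
}

.maximinAngle <- function(A, B) {
  # min over columns of A of the axial angle to the nearest column of B
  C <- abs(crossprod(A, B))
  min(acos(pmin(1, apply(C, 1L, max))) * 180 / pi)
}

#' Generate hypothetical directions by rigid rotation of an observed scheme
#'
#' Hypothetical directions are smoothing-only evaluation points obtained by
#' applying one rigid rotation to the whole observed scheme.  The rotation is
#' chosen by a seeded search (random candidates plus local refinement) to
#' maximize the minimum axial angle between any hypothetical direction and
#' the observed set, so the combined scheme fills the angular gaps.
#'
#' @param observed 3 x n matrix of observed directions.
#' @param nExtra how many hypothetical directions to keep (default all n).
#' @param seed integer seed for the candidate-rotation search (default 1).
#' @param nCandidates number of random candidate rotations (default 1000).
#' @return 3 x nExtra matrix of unit axes (z >= 0).
#' @export
generateHypotheticalDirections <- function(observed, nExtra = ncol(observed),
                                           seed = 1L, nCandidates = 1000L) {
  observed <- as.matrix(observed)
  if (ncol(observed) == 0L) stop("observed set must be nonempty")
  best <- withr_seed(seed, {
    bestR <- diag(3); bestVal <- -Inf
    for (i in seq_len(nCandidates)) {
      R <- .randomRotation()
      v <- .maximinAngle(R %*% observed, observed)
      if (v > bestVal) { bestVal <- v; bestR <- R }
    }
    # local refinement: shrinking random perturbations about the incumbent
    scale <- 0.1
    for (i in seq_len(200L)) {
      ax <- rnorm(3L); ax <- ax / sqrt(sum(ax^2))
      Rp <- .axisAngleRotation(ax, scale * rnorm(1L)) %*% bestR
      v <- .maximinAngle(Rp %*% observed, observed)
      if (v > bestVal) { bestVal <- v; bestR <- Rp } else scale <- scale * 0.99
    }
    bestR
  })
  H <- best %*% observed
  neg <- H[3L, ] < 0
  H[, neg] <- -H[, neg]
  unname(H[, seq_len(nExtra), drop = FALSE])
}

.axisAngleRotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3L], axis[2L], axis[3L], 0, -axis[1L],
                -axis[2L], axis[1L], 0), 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Add hypothetical directions to a protocol
#'
#' @param protocol a \code{\link{DWIProtocol}} without hypothetical entries.
#' @param nExtra number of hypothetical directions (default: one per
#'   observed DW direction).
#' @param seed seed for the rotation search.
#' @return a new \code{DWIProtocol} with the hypothetical entries appended;
#'   they reuse the (single) nonzero b-value of the scheme.
#' @export
addHypotheticalDirections <- function(protocol, nExtra = NULL, seed = 1L) {
  obs <- bValues(protocol) > 0 & !isHypothetical(protocol)
  U <- gradientDirections(protocol)[, obs, drop = FALSE]
  if (is.null(nExtra)) nExtra <- ncol(U)
  H <- generateHypotheticalDirections(U, nExtra = nExtra, seed = seed)
  b <- unique(bValues(protocol)[obs])
  if (length(b) != 1L) stop("hypothetical directions require a single-shell protocol")
  dwiProtocol(cbind(gradientDirections(protocol), H),
              c(bValues(protocol), rep(b, nExtra)),
              c(isHypothetical(protocol), rep(TRUE, nExtra)))
}

# ---- FSL-style bval/bvec text files ---------------------------------------

#' Read FSL-style bval/bvec files
#'
#' bvec files hold three whitespace-separated rows (x, y, z components);
#' bval files one row of b-values.  Directions are unit-normalized on read.
#'
#' @param bvalPath,bvecPath file paths.
#' @return a \code{\link{DWIProtocol}}.
#' @export
readBvalBvec <- function(bvalPath, bvecPath) {
  bvals <- scan(bvalPath, quiet = TRUE)
  rows <- lapply(readLines(bvecPath), function(l) scan(text = l, quiet = TRUE))
  rows <- rows[vapply(rows, length, 1L) > 0L]
  if (length(rows) != 3L) stop("bvec file must contain exactly three rows")
  bvecs <- do.call(rbind, rows)
  if (ncol(bvecs) != length(bvals))
    stop("bval and bvec files disagree on the number of acquisitions")
  dwiProtocol(bvecs, bvals)
}

#' Write FSL-style bval/bvec files
#'
#' Hypothetical directions are never written; they are an in-memory
#' smoothing construct, not acquired data.
#'
#' @param protocol a \code{\link{DWIProtocol}}.
#' @param bvalPath,bvecPath output file paths.
#' @return invisibly, the paths.
#' @export
writeBvalBvec <- function(protocol, bvalPath, bvecPath) {
  keep <- !isHypothetical(protocol)
  writeLines(paste(format(bValues(protocol)[keep], trim = TRUE), collapse = " "),
             bvalPath)
  B <- gradientDirections(protocol)[, keep, drop = FALSE]
  writeLines(apply(B, 1L, function(r) paste(format(r, digits = 10, trim = TRUE),
                                            collapse = " ")), bvecPath)
  invisible(c(bvalPath, bvecPath))
}
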