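# NIfTI + bval/bvec input-output and voxelwise volume fitting.

#' Read a diffusion-weighted volume with its gradient table
#'
#' @param niftiPath 4D NIfTI image (x, y, z, acquisition).
#' @param bvalPath,bvecPath FSL-style gradient table files.
#' @param maskPath optional 3D mask image; voxels with value > 0 are fitted.
#' @return list with \code{image} (4D array), \code{protocol}
#'   (\code{\link{DWIProtocol}}) and \code{mask} (logical 3D array).
#' @export
readDWI <- function(niftiPath, bvalPath, bvecPath, maskPath = NULL) {
  img <- RNifti::readNifti(niftiPath)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # plain array, no image metadata
  if (length(dim(arr)) != 4L) stop("expected a 4D diffusion volume")
  protocol <- readBvalBvec(bvalPath, bvecPath)
  if (length(bValues(protocol)) != dim(arr)[4L])
    stop("gradient table length does not match the 4th image dimension")
  mask <- if (is.null(maskPath)) array(TRUE, dim(arr)[1:3]) else
    as.array(RNifti::readNifti(maskPath)) > 0
  if (!all(dim(mask) == dim(arr)[1:3])) stop("mask dimensions do not match")
  list(image = arr, protocol = protocol, mask = mask, header = img)
}

#' Write a simulated diffusion volume
#'
#' Fills a small volume with independent noisy realizations of a scenario
#' voxel and writes the NIfTI image plus bval/bvec files.
#'
#' @param scenario output of \code{\link{makeScenario}}.
#' @param dim 3-vector of spatial dimensions (default c(2, 2, 1)).
#' @param seed integer seed.
#' @param prefix output path prefix; writes <prefix>.nii.gz, <prefix>.bval,
#'   <prefix>.bvec.
#' @return invisibly, the written paths.
#' @export
writeSimulatedDWI <- function(scenario, dim = c(2L, 2L, 1L), seed = 1L,
                              prefix = "simulated") {
  clean <- predictSignal(scenario$model, scenario$protocol)
  nvox <- prod(dim)
  arr <- withr_seed(seed, {
    a <- array(0, c(dim, length(clean)))
    for (v in seq_len(nvox)) {
      ijk <- arrayInd(v, dim)
      a[ijk[1L], ijk[2L], ijk[3L], ] <- addNoise(clean, scenario$model@sigma)
    }
    a
  })
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), nii)
  writeBvalBvec(scenario$protocol, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(c(nii, paste0(prefix, ".bval"), paste0(prefix, ".bvec")))
}

#' Fit the simplified model to every voxel of a volume
#'
#' Per masked voxel: S0 from the b = 0 mean, stage-one smoothing and
#' nuisance solution, rotation, simplified-model MCMC (with dynamic
#' stopping when configured), the 1- vs 2-fiber screen, and posterior
#' summarization.  Voxels whose total stick fraction comes out (near) zero
#' are recorded as isotropic (0 fibers) rather than fitted.
#'
#' @param image 4D array.
#' @param protocol a \code{\link{DWIProtocol}} (hypothetical directions are
#'   added automatically if absent).
#' @param mask logical 3D array (default: all voxels).
#' @param config an \code{\link{mcmcConfig}}.
#' @param kappa,kappa2 smoothing concentrations (defaults 50, 0.1).
#' @param seed master seed; per-voxel chain seeds derive from it.
#' @return list of class "fitReport": \code{voxels} (per-voxel records),
#'   \code{maps} (named list of 3D/4D parameter arrays: f1, f2, d, S0,
#'   nFibers, dyad1, dyad2) and \code{config}.
#' @export
fitVolume <- function(image, protocol, mask = NULL, config = mcmcConfig(),
                      kappa = 50, kappa2 = 0.1, seed = 1L) {
  dims <- dim(image)[1:3]
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!any(isHypothetical(protocol)))
    protocol <- addHypotheticalDirections(protocol)
  vox <- which(mask, arr.ind = TRUE)
  seeds <- withr_seed(seed, sample.int(.Machine$integer.max, nrow(vox)))
  maps <- list(f1 = array(NA_real_, dims), f2 = array(NA_real_, dims),
               d = array(NA_real_, dims), S0 = array(NA_real_, dims),
               nFibers = array(NA_real_, dims),
               dyad1 = array(NA_real_, c(dims, 3L)),
               dyad2 = array(NA_real_, c(dims, 3L)))
  records <- vector("list", nrow(vox))
  for (v in seq_len(nrow(vox))) {
    i <- vox[v, 1L]; j <- vox[v, 2L]; k <- vox[v, 3L]
    y <- image[i, j, k, ]
    cfg <- config; cfg$seed <- seeds[v]
    rec <- tryCatch({
      nu <- estimateNuisance(y, protocol, kappa = kappa, kappa2 = kappa2)
      if (nu@F < 0.01) {
        list(voxel = c(i, j, k), nFibers = 0L, S0 = nu@S0, d = nu@d, F = nu@F)
      } else {
        ch <- runSimplifiedMCMC(y, protocol, nu, cfg)
        post <- summarizePosterior(ch, nu)
        nf <- classifyFiberCount(ch, nu)
        list(voxel = c(i, j, k), nFibers = nf, S0 = nu@S0, d = nu@d, F = nu@F,
             f = post$fractions, directions = post$directions,
             summary = post$summary, stoppedAt = ch@stoppedAt,
             acceptance = acceptanceRates(ch))
      }
    }, error = function(e) list(voxel = c(i, j, k), error = conditionMessage(e)))
    records[[v]] <- rec
    maps$S0[i, j, k] <- rec$S0 %||% NA_real_
    maps$d[i, j, k] <- rec$d %||% NA_real_
    maps$nFibers[i, j, k] <- rec$nFibers %||% NA_real_
    if (!is.null(rec$f)) {
      maps$f1[i, j, k] <- rec$f[1L]; maps$f2[i, j, k] <- rec$f[2L]
      for (fb in 1:2) {
        dy <- rec$directions[, fb]
        if (dy[3L] < 0) dy <- -dy          # antipodal canonicalization z >= 0
        maps[[paste0("dyad", fb)]][i, j, k, ] <- dy
      }
    }
  }
  structure(list(voxels = records, maps = maps, config = unclass(config),
                 seed = seed), class = "fitReport")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the parameter maps of a fit report as NIfTI images
#'
#' @param report a fit report from \code{\link{fitVolume}}.
#' @param prefix output path prefix.
#' @return invisibly, the written paths.
#' @export
writeFitMaps <- function(report, prefix) {
  paths <- character(0)
  for (nm in names(report$maps)) {
    p <- paste0(prefix, "_", nm, ".nii.gz")
    RNifti::writeNifti(RNifti::asNifti(report$maps[[nm]]), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Serialize a fit report to JSON
#'
#' Drops the bulky per-voxel posterior summaries' sample matrices (none are
#' stored) and writes a lossless plain-text record of the per-voxel
#' estimates, decisions and configuration.
#'
#' @param report a fit report.
#' @param path output .json path.
#' @return invisibly, the path.
#' @export
writeFitReport <- function(report, path) {
  jsonlite::write_json(
    list(config = report$config[!vapply(report$config, is.null, TRUE)],
         seed = report$seed,
         voxels = lapply(report$voxels, function(r) {
           r$summary <- if (!is.null(r$summary)) as.list(r$summary) else NULL
           r
         })),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
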