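# ballstick

Bayesian estimation of crossing white-matter fibers from single-shell
diffusion-weighted MRI (dMRI) with the Ball-and-Stick partial-volume model,
built for the two-fiber case that dominates crossing-fiber voxels in the
brain.

## The model and the two-stage estimator

Per voxel, the measured intensity along gradient direction r_i with
diffusion weighting b (s/mm^2) is modeled as

    S_i = S0 [ (1 - f1 - f2) exp(-b d)
             + f1 exp(-b d (r_i . t_1)^2)
             + f2 exp(-b d (r_i . t_2)^2) ] + eps_i,   eps_i ~ N(0, sigma^2)

with baseline S0, diffusivity d (mm^2/s), stick axes t_k (unit vectors,
elevation/azimuth angles (theta_k, phi_k)) and volume fractions f_k.
Sampling all nine parameters by MCMC is slow and fragile, so `ballstick`
estimates in two stages:

1. **Closed-form nuisance stage.** The spherical mean of the DW signal is
   orientation-free: `Sbar = S0[(1-F) e^(-bd) + F sqrt(pi) erf(sqrt(bd)) /
   (2 sqrt(bd))]` with F = f1 + f2, and the signal maximum — attained on
   the *longitudinal axis*, the common perpendicular of the two sticks —
   is `max(S) = S0[(1-F) e^(-bd) + F]`. Solving the two identities yields
   d and F without any regression. The maximum's magnitude and direction
   are estimated from von-Mises-kernel-smoothed signals (concentrations
   kappa = 50 and kappa2 = 0.1), with *hypothetical* smoothing-only
   directions filling the angular gaps of the acquisition scheme.
2. **Reduced MCMC stage.** Rotating the longitudinal axis onto +Z puts the
   crossing-fiber plane onto the XY-plane, so each fiber is one azimuth;
   an adaptive Metropolis-within-Gibbs sampler (compiled core, 0.44 target
   acceptance, diminishing adaptation, Gibbs step for the noise precision)
   samples just (f1, phi'1, phi'2, sigma), with f2 = F - f1. A Geweke-based
   dynamic stopping rule ends chains at the voxel level, and a screen on
   the chain flags over-fitted one-fiber voxels.

The full nine-parameter sampler is included (`runFullMCMC()`) for
head-to-head benchmarking, along with a seeded synthetic-voxel generator,
a replication engine reproducing bias/posterior-sd benchmark tables, and
NIfTI + FSL-style bval/bvec IO for fitting volumes.

## Worked example

```r
library(ballstick)
scenario <- makeScenario("paper-default-64")   # S0 400, b 1500, d 1/1500,
signal   <- simulateVoxel(scenario, seed = 42) # f (0.4, 0.5), 60/120 deg, SNR 20
nuis  <- estimateNuisance(signal, scenario$protocol)
nuis
#> NuisanceEstimates: S0 = 408.79, d = 0.0006776 mm^2/s, F = 0.867
#>   longitudinal axis: theta = 80.1, phi = 189.1
chain <- runSimplifiedMCMC(signal, scenario$protocol, nuis,
                           mcmcConfig(nIter = 20000, thin = 5, seed = 42))
fit <- summarizePosterior(chain, nuis)
print(fit$summary, digits = 3)
#>   parameter  median     sd
#> 1        f1   0.379 0.0212
#> 2        f2   0.488 0.0212
#> 3    theta1   5.393 0.3876
#> 4      phi1  66.243 2.6911
#> 5    theta2  -4.374 0.3216
#> 6      phi2 125.189 2.0718
#> 7     sigma   8.065 0.2638
matchFibers(fit$directions, scenario$model@orientations)$distances
#> [1] 8.221070 6.811015
```

Reading the output: stage one recovered the baseline (408.8 from the eight
b = 0 volumes), a diffusivity of 0.00068 mm^2/s (truth 0.00067) and a total
stick fraction of 0.87 (truth 0.9), with the longitudinal axis 9.9 degrees
off +Z. The sampled fractions (0.379, 0.488) sit close to the generating
(0.4, 0.5), and the back-rotated fiber azimuths (66.2, 125.2 degrees)
bracket the true 60/120-degree crossing; the matched axial angular errors
are 8.2 and 6.8 degrees. The sigma row is the *effective* noise scale
under the default sharp precision prior (see the methods vignette), not an
estimate of the generating sigma = 20.

A thin command-line front end covers simulation, volume fitting and the
replication experiments:

```sh
exec/ballstick simulate  --scenario paper-default-64 --seed 1 --out sim
exec/ballstick fit       --dwi sim.nii.gz --bval sim.bval --bvec sim.bvec --out maps
exec/ballstick experiment --scenario paper-default-64 --models simplified,full --fast --out table.csv
```

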