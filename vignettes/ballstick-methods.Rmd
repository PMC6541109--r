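---
title: "Two-stage estimation of crossing fibers with the simplified Ball-and-Stick model"
author: "ballstick package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage estimation of crossing fibers with the simplified Ball-and-Stick model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ballstick)
```

# The model

A single-shell diffusion-weighted acquisition measures, per voxel, one
intensity $S_i$ for each gradient direction $r_i$ (a unit vector) at
diffusion weighting $b_i$ (s/mm^2). The Ball-and-Stick partial-volume model
splits the voxel into an isotropic "ball" compartment and $L$ anisotropic
"stick" compartments with axes $t_k$ and volume fractions $f_k$:

$$
S_i = S_0\Big[\big(1-\textstyle\sum_k f_k\big)\,e^{-b_i d}
      + \textstyle\sum_k f_k\, e^{-b_i d\,(r_i\cdot t_k)^2}\Big]
      + \varepsilon_i ,
\qquad \varepsilon_i \sim \mathcal N(0,\sigma^2)\ \text{i.i.d.}
$$

$(r_i\cdot t_k)^2 = \cos^2\Delta_{ik}$ depends only on the axial angle
between gradient and stick, so the signal is antipodally symmetric in both
arguments. Angles follow the elevation convention throughout:
$\theta \in [-90^\circ, 90^\circ]$ is measured from the XY-plane (so
$\theta = 90^\circ$ is $+Z$), $\phi \in [0^\circ, 360^\circ)$ from the
X-axis; fiber axes are reported with $\phi$ canonicalized to
$[0^\circ, 180^\circ)$ to resolve the antipodal ambiguity.

Fitting all nine parameters of the two-fiber model
$(S_0, d, f_1, f_2, \theta_1, \phi_1, \theta_2, \phi_2, \sigma)$ by MCMC is
slow and, in a weakly identified nonlinear regression, fragile. The package
therefore implements a two-stage estimator that removes the five nuisance
parameters in closed form and samples only what describes the fibers.

# Stage one: nuisance parameters from signal shape

**Spherical mean.** For a fixed $b$, averaging the model signal over
uniformly distributed gradient directions integrates the stick term over
the angle density $f(\Delta)=\tfrac12\sin\Delta$, giving

$$
\bar S \;=\; S_0\Big[(1-F)\,e^{-bd}
        + F\,\frac{\sqrt{\pi}\,\mathrm{erf}(\sqrt{bd})}{2\sqrt{bd}}\Big],
\qquad F = \textstyle\sum_k f_k ,
$$

which is *independent of the fiber orientations* (`theoreticalMean()`,
verified in the tests against numerical integration of
$E[e^{-bd\cos^2\Delta}]$). The empirical counterpart is the plain mean of
the raw diffusion-weighted intensities (`sphericalMean()`).

**Signal maximum.** In a two-fiber voxel the diffusion signal is maximal
along the *longitudinal axis* $r_l$, the common perpendicular of the two
sticks, where both attenuation exponents vanish:

$$
\max(S) = S_0\big[(1-F)e^{-bd} + F\big].
$$

**Solving for $(d, F)$.** With $S_0$ known (benchmarks) or estimated as the
mean of the $b=0$ intensities (volume fitting), the two identities form a
simultaneous system. `solveDF()` eliminates $F$ through the maximum
equation, $F(x) = (\max(S)/S_0 - e^{-x})/(1 - e^{-x})$ with $x = bd$, and
finds the root of the mean-equation residual by bracketed `uniroot` on
$x \in [10^{-6}, 20]$ to $10^{-12}$; the residual is monotone in $x$
(tested on a grid), so the bracket is safe. Degenerate inputs are clipped
with a warning: $\max(S) > S_0 \to S_0$; $\max(S) \le \bar S$ returns
$F = 0$ (isotropic) with a ball-only inversion for $d$. Below
$bd = 10^{-8}$ the erf factor switches to a sixth-order series to avoid
$0/0$.

# Smoothing on the sphere

Both $\max(S)$ and $r_l$ are extreme-value statistics, so raw noisy maxima
are biased upward and angularly unstable. The package smooths the signal
over gradient directions with a von-Mises kernel,

$$
S^{\text{smooth}}_j = \frac{\sum_i w_{ij} S_i}{\sum_i w_{ij}},
\qquad w_{ij} = \frac{e^{\kappa \cos x_{ij}}}{2\pi I_0(\kappa)},
$$

where $x_{ij}$ is the *axial* angular distance
$\arccos|r_i \cdot r_j|$ — the signal depends on $\cos^2$ of the angle, so
a polar distance would mix hemispheres incoherently at small $\kappa$. The
normalization cancels in the weighted mean; internally the exponent is
max-subtracted so concentrations up to $\kappa \sim 700$ do not overflow.
Every smoothed value is a convex combination of the observations.

**Hypothetical directions.** The argmax over a 64-direction scheme is
limited by its angular spacing. `addHypotheticalDirections()` appends
smoothing-only evaluation directions obtained by one rigid rotation of the
whole observed scheme, the rotation chosen by a seeded search (1000 random
candidates plus local refinement) to maximize the minimum axial angle to
the observed set, filling the scheme's gaps. Hypothetical directions never
carry data; they are only evaluation points.

**Kernel concentrations.** Two different concentrations are deliberately
used. The maximum magnitude is estimated with $\kappa = 50$ (useful range
roughly 35–70): wide enough to average noise at the peak, narrow enough not
to flatten it. The axis direction is estimated with a very diffuse kernel,
$\kappa_2 = 0.1$: the argmax then responds to the global shape of the
signal surface rather than to single noisy measurements. Both are exposed
everywhere (`kappa`, `kappa2`).

**Discrete argmax vs continuous refinement.** The smoothed field is defined
for arbitrary target directions, so after locating the best grid direction
the axis estimator refines it by a local continuous maximization
(Nelder–Mead on the tangent plane; `refine = TRUE`, the default for
`estimateLongitudinalAxis()`). Without refinement the axis inherits the
grid granularity — on the package's combined 64+64 scheme the nearest grid
axis to a benchmark truth sits about 6 degrees away, an error that
propagates into every fiber orientation. The *magnitude* estimator
`estimateMaxSignal()` keeps the discrete maximum by default
(`refine = FALSE`): the $\kappa$ guidance above is an empirical calibration
around that estimator, whose small peak-flattening bias offsets the upward
noise-selection bias of a maximum statistic. Even refined, a residual
systematic of about 2 degrees remains in the axis at 50-degree fiber
separation: the continuous maximum of a kernel average over a *discrete*
64-point observation set does not sit exactly on the true axis.

# Stage two: rotation and sampling

**Rotation.** `rotationToZ()` maps $\hat r_l$ onto $+Z$ (azimuthal rotation
into the XZ-plane, then a rotation about Y), so the crossing-fiber plane
becomes the XY-plane and each fiber axis reduces to a single azimuth
$\phi'_k \in [0, \pi)$. The simplified mean model, evaluated on the rotated
gradients $r'_i$, is

$$
S_i = \hat S_0\Big[(1-\hat F)e^{-b_i \hat d}
    + f_1 e^{-b_i \hat d (r'_{i,x}\cos\phi'_1 + r'_{i,y}\sin\phi'_1)^2}
    + (\hat F - f_1) e^{-b_i \hat d (r'_{i,x}\cos\phi'_2 + r'_{i,y}\sin\phi'_2)^2}\Big],
$$

with $f_2 = \hat F - f_1$ by construction. Four parameters
$(f_1, \phi'_1, \phi'_2, \sigma)$ remain.

**Samplers.** Both models use the same adaptive Metropolis-within-Gibbs
core (compiled):

* symmetric Gaussian random-walk proposals per parameter; out-of-support
  candidates ($f_1 \notin [0, \hat F]$, $\phi' \notin [0,\pi)$; full-model
  bounds below) carry zero prior mass and are rejected, preserving the
  symmetric-proposal acceptance ratio;
* proposal scales adapted every 50 iterations: multiplied (divided) by
  $\delta$ when the batch acceptance exceeds (falls short of) the 0.44
  target, with $\delta = \exp(\min(0.01, 1/\sqrt{\text{batch}}))$, so
  adaptation diminishes;
* the noise precision $\sigma^{-2}$ is updated by a Gibbs step under a
  conjugate Gamma(200, 1) prior: conditional
  $\text{Gamma}(200 + n/2,\; 1 + \text{SSR}/2)$. These hyperparameters make
  the prior informative (it centers the effective $\sigma$ near 8 at the
  benchmark's $n$ and SSR rather than at the generating 20), which sharpens
  the fiber-parameter posteriors; the replicated posterior spread of $f_1$
  under this prior is what the package's benchmark tables reproduce. An
  alternative reading — an Inverse-Gamma density on the precision itself —
  is implemented as `precisionPrior = "invgamma"`; its conditional is
  generalized-inverse-Gaussian and is updated by an exact slice-sampling
  step on $\log\sigma^2$ (log-concave, stepping-out + shrinkage). Both
  hyperparameters are exposed (`priorShape`, `priorRate`).

Full-model priors are weakly informative uniforms:
$S_0 \sim U(0, 2\max S_i)$, $d \sim U(10^{-5}, 10^{-2})$ mm^2/s,
$f_1, f_2 \sim U(0,1)$ restricted to $f_1 + f_2 \le 1$, azimuths uniform on
$[0, 2\pi)$, elevations area-uniform (prior density $\propto \cos\theta$,
entering the acceptance ratio).

**Initialization** is deterministic: $f_1 = \hat F/2$; the azimuths from a
36-point grid scan of the rotated-frame residual over ordered azimuth
pairs (fallback $\pi/4, 3\pi/4$); $\sigma$ at $5\%$ of $\hat S_0$; the full
model starts at the stage-one estimates and their back-rotated grid
azimuths. A deterministic start avoids symmetric-mode trapping and makes
chains bit-reproducible given the seed.

**Summaries.** After discarding the first half and thinning by 10
(defaults), `summarizePosterior()` reports medians and standard deviations.
The two sticks are exchangeable (swapping $(f_1,\phi'_1,\phi'_2)$ for
$(\hat F - f_1, \phi'_2, \phi'_1)$ leaves the likelihood unchanged), so
draws are first relabeled to $\phi'_1 \le \phi'_2$ (full model: by axial
azimuth). Orientations are summarized by the principal axis of the mean
dyadic tensor $E[t t^\top]$ — the standard wrap-safe axial summary — and
back-rotated through $R_{\text{rot}}^\top$; azimuth dispersion is computed
on wrapped deviations about that axis.

# Convergence control and model screening

`gewekeZ()` compares early (10%) and late (50%) window means standardized
by spectral-density-at-zero estimates (Bartlett window over the first 4% of
lags; a zero-variance segment returns $z = 0$, a constant chain being
trivially converged). With a `stoppingRule()`, chains run in 5000-iteration
segments and stop once every parameter has $|z| < 2$ (at least 10000
iterations); on the default two-fiber benchmark the median stop is near
15000 of a 100000 budget.

`classifyFiberCount()` screens a two-fiber fit for one-fiber data: declare
one fiber when the posterior median of the smaller fraction
$\min(f_1, \hat F - f_1)$ falls below 0.2, or the median inter-azimuth
angle below 45 degrees. Both thresholds are calibrated on the benchmark
voxels at SNR 20: one-fiber data typically clip $\hat F$ at 1 (the ring
maximum of a single stick overshoots $S_0$ under noise), so the
$\sim 0.1$ ball fraction leaks into the surplus stick and partial-overlap
fits spread it to $\sim 0.25$ at separations under 45 degrees — which is
also the angular resolution limit of a 64-direction shell at SNR 20. A
side effect is deliberate: genuinely crossing fibers tighter than 45
degrees are reported as one fiber. Note the surplus stick's wandering
azimuth *delays* Geweke stopping on over-fitted voxels; the screen, not
the stopping rule, is the over-fitting detector.

# The synthetic-data generator

`makeScenario()` registers the benchmark conditions used throughout:
$S_0 = 400$, $b = 1500$ s/mm^2, $d = 1/1500$ mm^2/s (so $bd = 1$), i.i.d.
Gaussian noise at SNR $= S_0/\sigma = 20$, and 64 (or 128) evenly
distributed gradient directions built once by electrostatic-repulsion
minimization of the axes plus their antipodes from a deterministic
Fibonacci start — the package's fixed gradient table, playing the role a
published scheme plays in practice — with an equal number of hypothetical
directions appended. The two-fiber default puts the sticks in the XY-plane
at azimuths 60 and 120 degrees with $f = (0.4, 0.5)$; separation variants
place them symmetrically about 90 degrees; three three-fiber stress
scenarios and a one-fiber voxel complete the registry. Replication
experiments (`runExperiment()`) simulate the diffusion-weighted directions
only and condition on the known $S_0$; the general tool path
(`writeSimulatedDWI()`, `fitVolume()`) includes 8 $b=0$ volumes and
estimates $S_0$ from them. The $b=0$ anchoring matters for the full model:
without it $S_0$ is weakly identified against $d$ and $F$ and drifts
upward, depressing the fraction estimates — the benchmark tables are run
without $b=0$ volumes, which is exactly the regime in which the full
nine-parameter sampler shows its characteristic negative fraction bias.

What the generator does **not** emulate: Rician/noncentral-$\chi$ noise
(Gaussian is assumed throughout, a high-SNR approximation), spatial
correlation between voxels, multi-shell acquisitions, fiber dispersion or
fanning, motion/eddy artifacts, and scanner-specific gradient
nonuniformity. Passing benchmarks therefore demonstrates correctness of
the estimator under its own assumptions, not robustness to real-data
violations of them.

# Replication experiments and their scale

`runExperiment()` simulates replicate voxels (noise seeds shared across
smoothing levels and models, a paired design that removes between-cell
Monte-Carlo variation), runs the full pipeline per replicate, matches
estimated to true fibers by minimum-average-angle permutation
(`matchFibers()`, null slots at 90 degrees when counts differ), and
aggregates bias (estimate − truth) and posterior-sd cells
(`experimentTable()`). `runThreeFiberExperiment()` fits the two-fiber
pipeline to three-fiber data and reports per-true-direction medians, IQRs
and match counts.

The package's own test suite and the `scripts/acceptance.R` benchmark use
25 replicates of 20000-iteration chains for the sampled tables (50 for the
angular-separation comparisons), 100 replicates for the smoothing-only
quantities, and 100 replicates for the three-fiber stress test; a
full-scale run (100 replicates, 100000 iterations, thinning 10) is a
matter of passing different arguments.

# Known limitations

* The three-fiber stress scenarios are deliberately misspecified, and with
  three equal orthogonal sticks the $\kappa_2 = 0.1$ smoothed field is
  maximized near the $(1,1,1)$-type diagonals rather than at any fiber
  axis (three moderate lobes outweigh one aligned lobe for any
  $\kappa_2 \lesssim 2.6$), so the fitted plane contains no true
  direction; the fraction estimates remain informative, the orientations
  do not.
* The axis estimator retains a degree-scale systematic tied to the
  discreteness of the observation set (see above); its replicated accuracy
  is a property of the specific gradient table.
* Conditioning stage two on point estimates of the nuisance parameters
  means the fiber-parameter posteriors do not propagate stage-one
  uncertainty.
* Label relabeling by azimuth order is exact for well-separated modes;
  heavily overlapping azimuth posteriors (near-parallel fibers) make the
  per-fiber marginals, like the fibers themselves, poorly defined.
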