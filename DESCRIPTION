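Package: ballstick
Title: Simplified Two-Fiber Ball-and-Stick Modeling of Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of crossing white-matter fibers from single-shell
    diffusion-weighted MRI with the Ball-and-Stick partial-volume model.
    Implements a two-stage simplified estimator: closed-form recovery of the
    nuisance parameters (baseline signal, diffusivity and total stick
    fraction) from the spherical mean and the von-Mises-smoothed signal
    maximum, rotation of the crossing-fiber plane onto the XY-plane, and
    adaptive Metropolis-within-Gibbs sampling of the remaining fiber
    parameters with Geweke-based dynamic stopping. The full nine-parameter
    Ball-and-Stick sampler is included for head-to-head benchmarking, along
    with a seeded synthetic-voxel generator, replication experiments, and
    NIfTI/bval/bvec input-output for volume fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
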