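Package: SpecSR
Title: Spectrum-Fitting Super-Resolution of 3D Magnetic Resonance Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Super-resolution of anisotropic 3D magnetic resonance volumes by
    spectrum extrapolation. Implements a convex reconstruction model that
    combines fidelity to the measured low-frequency spectrum with a known
    object-support (boundary) constraint, isotropic total-variation
    regularization and a tensor trace-norm (low-rank) prior, solved by the
    alternating direction method of multipliers. The classic Gerchberg
    projection-onto-convex-sets algorithm and interpolation, zero-padding,
    TV and low-rank-plus-TV baselines are included, together with a
    synthetic phantom simulator of the anisotropic slice-selection
    acquisition process and an evaluation harness scoring peak
    signal-to-noise ratio inside the object region.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, RNifti, jsonlite, yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'core-ops.R'
    'phantom.R'
    'spectrum.R'
    'gerchberg.R'
    'lrtvg.R'
    'baselines.R'
    'evaluation.R'
    'io.R'
    'cli.R'
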