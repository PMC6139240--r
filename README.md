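# SpecSR — spectrum-fitting super-resolution of anisotropic MR volumes

MR volumes are routinely acquired with thick slices: the through-slice
voxel size is β times the in-plane size, so only a low-frequency band of 3D
k-space is measured along each acquisition's slice-select axis. Even two
volumes with orthogonal slice directions leave the diagonal high-frequency
corner of the spectrum unmeasured. `SpecSR` reconstructs an isotropic
volume by *extrapolating the spectrum*, for researchers who have two (or
one) anisotropic acquisitions of the same field of view plus an outer
boundary label of the imaged object.

The core model is a convex program over the full spectrum **f** (image
**x** = G **f**, G the inverse unitary DFT):

```
minimize   λ_TV ‖x‖_TV  +  (λ_LR/3) Σᵢ ‖unfoldᵢ(Mᵢ)‖_*
         + ½ ‖f₀′ − R_Ω f‖²  +  (ε/2) Σᵢ (‖x − mᵢ + vᵢ‖² − ‖vᵢ‖²)
subject to x = G f,   R_Γ̄ x = 0
```

— spectrum fidelity on the measured band Ω (after slice-profile
deconvolution, f₀′), a hard object-support constraint on Γ, isotropic total
variation, and a tensor trace-norm (low multilinear rank) prior through
per-mode slack copies Mᵢ. It is solved by ADMM; each block update is the
exact minimizer of the augmented Lagrangian (a diagonal spectrum solve, a
conjugate-gradient image solve, group soft-thresholding for TV, and
singular value thresholding for the rank prior). With `λ_TV = λ_LR = 0` the
model reduces to the constraint set of the classic Gerchberg POCS
algorithm, which is also implemented directly, along with
nearest-neighbour, cubic, zero-padding, TV and low-rank+TV baselines and a
synthetic phantom simulator of the anisotropic acquisition process.

## A worked example

```r
library(SpecSR)

p   <- makePhantom(c(48L, 48L, 48L), style = "t1like", seed = 1)   # truth + support
sim <- simulateAcquisition(p, beta = 4, noisePct = 1, seed = 1001) # two orthogonal views

psnrInRegion(zeroPadSR(sim$spectrum), truth(p), support(p))
#> [1] 21.50104

rec <- lrtvg(sim$spectrum, support(p),
             solverConfig(lambdaTV = 1e-2, lambdaLR = 1e-1, epsilon = 0.01,
                          maxIter = 150L, tol = 1e-5))
rec
#> SolverResult: 94 iterations, converged=TRUE, final cost 105.875
psnrInRegion(volume(rec), truth(p), support(p))
#> [1] 24.62012
```

The phantom is a nested-ellipsoid head surrogate degraded by β = 4
block-mean slice averaging plus 1% Gaussian noise. Zero-padding the
measured band gives 21.5 dB inside the object region; the regularized
spectrum-fitting reconstruction recovers a further ~3 dB by extrapolating
the unmeasured frequencies under the TV, low-rank and boundary priors.
PSNR is always computed inside the true support, with the peak set to the
truth's global maximum.

A command-line front end wrapping the same functions is installed with the
package (`system.file("cli", "specsr", package = "SpecSR")`) with verbs
`simulate`, `reconstruct`, `evaluate` and `experiment`; volumes, masks and
spectra travel as NIfTI-1 files (spectra as a real/imaginary/mask triple).
See the vignette `spectrum-fitting-super-resolution` for the model,
conventions and limitations.

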