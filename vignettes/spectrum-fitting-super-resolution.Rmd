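---
title: "Spectrum-fitting super-resolution of anisotropic MR volumes"
author: "SpecSR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectrum-fitting super-resolution of anisotropic MR volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SpecSR)
```

## The problem

Clinical MR volumes are usually anisotropic: the through-slice voxel size is
$\beta$ times the in-plane size because thick slices buy signal-to-noise.
In the frequency domain this means only a low-frequency band
$\Omega_d$ along each acquisition's through-slice axis is measured. Even
with two volumes acquired with orthogonal slice-select directions, the union
$\Omega = \Omega_1 \cup \Omega_2$ leaves the diagonal high-frequency corner
of 3D k-space unmeasured. Super-resolution in this setting is spectrum
extrapolation: estimate the missing coefficients and return an isotropic
volume.

`SpecSR` implements a convex reconstruction model that combines four pieces
of prior knowledge:

$$
\min_{\mathbf f}\;
\lambda_{TV}\,\|\mathbf x\|_{TV}
\;+\;\frac{\lambda_{LR}}{3}\sum_{i=1}^{3}\big\|\mathrm{unfold}_i(\mathcal M_i)\big\|_*
\;+\;\frac12\big\|\mathbf f_0' - R_\Omega \mathbf f\big\|_2^2
\;+\;\frac{\epsilon}{2}\sum_{i=1}^{3}\Big(\|\mathbf x-\mathbf m_i+\mathbf v_i\|_2^2-\|\mathbf v_i\|_2^2\Big)
$$

subject to $\mathbf x = G\mathbf f$ (the image is the inverse DFT of the
spectrum) and $R_{\bar\Gamma}\,\mathbf x = 0$ (the image vanishes outside a
known object support $\Gamma$). Here $\mathbf f_0'$ is the observed spectrum
after slice-profile deconvolution, $R_\Omega$ restricts to the measured
band, $\|\cdot\|_{TV}$ is isotropic total variation, and the
$\mathcal M_i$ are per-mode slack copies of the image whose nuclear norms
form a weighted tensor trace norm (the convex surrogate of multilinear
rank). The model contains three classical methods as special cases:

* $\lambda_{TV}=\lambda_{LR}=0$: the constraint set of the Gerchberg
  projection-onto-convex-sets (POCS) algorithm — spectrum fidelity on
  $\Omega$ plus support on $\Gamma$;
* $\lambda_{LR}=\epsilon=0$: TV-regularized spectrum fitting with the
  boundary prior (`tvg()`);
* dropping the spectrum fidelity for an image-domain fidelity gives the TV
  and low-rank-plus-TV baselines (`tvSR()`, `lrtvSR()`).

## The observation model

`degrade()` maps an isotropic truth to one anisotropic observation:
circular convolution along the through-slice axis with the slice profile —
a length-$\beta$ boxcar for the ideal rectangular profile, or a discretized
Gaussian of FWHM $\beta$ voxels — followed by block-aligned decimation by
$\beta$ and i.i.d. Gaussian noise with standard deviation
$\sigma = \mathrm{noise}\%/100 \times \max(\text{truth})$. The percent
convention follows the phantom databases this simulator stands in for; the
noise is added in image space and carried into the spectrum by linearity.

`observedSpectrum()` embeds the unitary DFT of the low-resolution volume on
the high-resolution grid. Two numerical conventions matter here and both
are fixed by exactness requirements rather than taste:

* **Scaling.** Coefficients are scaled by $\sqrt\beta$, which is the unique
  scale making a noise-free $\beta=1$ observation embed exactly as
  `dft3(truth)` under the unitary DFT convention.
* **Phase.** Block-aligned decimation represents each block by its first
  voxel while the block mean "lives" at the block centre, a half-block
  shift that appears as a linear phase $e^{i\pi k(\beta-1)/N}$. The
  embedding compensates it, so the slice-profile response $P_\Xi$ is the
  real Dirichlet (periodic sinc) kernel and reconstructions align with the
  truth grid.

The measured band along the through-slice axis is the $N/\beta$ lowest
signed frequencies. When $N/\beta$ is even the low-resolution Nyquist bin
has no conjugate partner on the target grid and is dropped to preserve
conjugate symmetry (at $\beta=1$ it is the target grid's own self-conjugate
Nyquist plane and is kept). Out-of-band truth energy aliases into the band;
this is part of the measurement model, not an artifact.

`assembleSpectrum()` deconvolves each observation's embedding by its own
profile response and averages the deconvolved coefficients where bands
overlap. Averaging after deconvolution (rather than before) keeps the fused
coefficients unbiased on $\Omega_1\cap\Omega_2$, where the two views carry
different profile attenuations. Indices where a profile response falls
below 0.05 in magnitude are removed from the band instead of divided,
bounding the noise amplification of the element-wise division; the
rectangular profile never reaches this floor inside its band (its in-band
minimum is $\approx 2/\pi$), so the guard matters only for wide Gaussian
profiles. All spectrum-domain methods — zero-padding, the Gerchberg
iteration, `tvg()` and `lrtvg()` — consume the same deconvolved
$\mathbf f_0'$, so their comparisons isolate the priors rather than the
preprocessing.

## The solver

The model is solved by ADMM on its augmented Lagrangian with splits
$Y = L\mathbf x$ (TV), $\mathbf x = G\mathbf f$ (spectrum consensus),
$R_{\bar\Gamma}\mathbf x = 0$ (support) and the per-mode slacks. Each block
update is the exact minimizer of the augmented Lagrangian over its block —
a property the test suite verifies directly with finite-difference
gradients and random-perturbation probes:

* $\mathbf f$: a per-coefficient diagonal solve, denominator $1+\rho$ on
  $\Omega$ and $\rho$ on $\bar\Omega$;
* $\mathbf x$: a symmetric positive-definite system
  $(3\epsilon I+\rho I+\rho R_{\bar\Gamma}+\rho L^TL)\mathbf x=\mathbf b$
  solved by warm-started conjugate gradients;
* $Y$: per-voxel group soft-thresholding at $\lambda_{TV}/\rho$;
* $\mathcal M_i$: singular value thresholding of the mode-$i$ unfolding at
  $\lambda_{LR}/(3\epsilon)$, computed through the Gram matrix of the
  shorter side (exact and much faster for $N\times N^2$ unfoldings);
* dual ascent for $\mathbf z$, $\boldsymbol\alpha$, $\boldsymbol\gamma$
  with step $\rho$ and for the slack multipliers $\mathbf v_i$ with step 1.

**Differences.** $\nabla_d$ is the forward difference with periodic
boundary. Periodicity makes $L^TL$ circulant, hence diagonal under the DFT,
which is what keeps the $\mathbf x$-system well conditioned (its spectrum
lies in $[3\epsilon+\rho,\ 3\epsilon+14\rho]$) and CG fast.

**Inner tolerance.** The CG solve uses a relative residual tolerance of
$10^{-4}$ by default. Tightening it to $10^{-6}$ changes reconstructions at
the fourth decimal of PSNR while nearly doubling runtime; block-optimality
tests override it to $10^{-12}$ where exactness is the point.

**Initialization.** The solver starts from the support-projected zero-fill
$\mathbf x_0 = P_\Gamma\,\mathrm{IDFT}(\mathbf f_0')$,
$\mathbf f_0=\mathrm{DFT}(\mathbf x_0)$, with all other variables zero.
This point satisfies both hard constraints, so for every converged run the
final objective cannot exceed the initial one (the solver returns the
objective minimizer over a feasible set containing the start) — initializing
at the raw zero-fill instead makes the initial spectrum-fidelity term
exactly zero and that comparison meaningless.

**Stopping.** Iterations stop when the relative change of the objective
falls below `tol` ($10^{-7}$ by default); the TV-split, spectrum-consensus
and support residual norms are recorded per iteration. The returned volume
receives a final hard projection $P_\Gamma \mathbf x$ so the support model
holds exactly.

**Penalty weight.** $\rho$ is fixed (default 1) with no residual-balancing
adaptation. In the pure-constraint regime $\lambda_{TV}=\lambda_{LR}=0$ —
used when cross-checking against the Gerchberg iteration — the objective
(the spectrum misfit alone) can reach machine zero while the constraint
duals are still converging, so the objective-change stopping rule can fire
early. Equivalence checks therefore run a fixed iteration budget with a
small penalty ($\rho = 0.1$), which reaches the POCS limit fastest there;
the recorded residual norms expose this regime in any run.

**Default $\epsilon = 0.01$.** The slack coupling must be weak relative to
the data fidelity; the sensitivity experiment below shows PSNR degrading
once $\epsilon$ grows to order 10.

## What the phantom emulates — and what it does not

`makePhantom()` builds nested ellipsoids with piecewise-constant
intensities: an outer shell (the support), a parenchyma shell and a fluid
core, with the contrast ordering inverted between `t1like` (bright
parenchyma, dark fluid) and `t2like` (dark parenchyma, bright fluid),
optionally with small contrast-inverted lesion blobs. It reproduces the
features the method's priors respond to — compact support with a margin
from the FOV boundary, sharp edges (TV), approximate low multilinear rank
(smooth ellipsoidal geometry), inverted modality contrast — and is exactly
piecewise constant, which slightly flatters TV regularization relative to
real tissue. It has no texture, no partial-volume ramps, no bias field and
no Rician noise floor, so passing tests demonstrate correctness of the
implementation and the qualitative behavior of the priors, not clinical
performance.

## Experiment sizes and settings

The experiment driver works at desk scale. The defaults are a $48^3$ grid,
$\beta = 4$, 1% noise, and two orthogonal views (through-slice axes 3 and
2); single reconstructions remain comfortable up to $128^3$. Per-method
regularization weights are selected by grid search maximizing PSNR inside
the support — the in-silico analogue of tuning weights per input image —
over log-spaced grids, five points across four decades per weight
($\lambda_{TV} \in 10^{[-4,0]}$, $\lambda_{LR} \in 10^{[-3,1]}$). Grid-search
runs use `maxIter = 120`, `tol = 1e-5`, which places candidates within
about 0.1 dB of their converged PSNR; definitive single runs use the full
`tol = 1e-7`.

PSNR is computed inside the true support only, with the peak taken as the
global maximum of the ground truth (the peak convention is not standardized;
this one makes values self-consistent across methods and noise levels).
Boundary-robustness sweeps perturb the support by thresholding the signed
Euclidean distance from the boundary — implemented exactly as
dilation/erosion with a digital Euclidean ball — and always score PSNR in
the *true* support. The asymmetry of the boundary prior shows clearly:
shrinking the mask removes true signal from the model and collapses the
reconstruction by an order of 15 dB, while dilating by two voxels only
weakens a prior and costs about one decibel. That one-decibel dilation cost
is stable across grid sizes (48–64 voxels), noise levels (0–1%) and
regularization weights on this phantom; its compact, high-contrast outer
rim sits directly on the support boundary, which makes the exact-boundary
constraint unusually informative compared with smoother anatomies, where
the reported dilation penalty is smaller.

## Known limitations

* The blur kernel is assumed known (no blind deconvolution) and the noise
  Gaussian, as in the model's fidelity term.
* The support mask must not underestimate the object; the boundary sweep
  quantifies how sharply performance collapses when it does.
* Nuclear-norm SVT dominates per-iteration cost at large sizes
  ($O(N^4)$ per mode); the spectrum steps are $O(N^3\log N)$.
* POCS-limit equivalence holds for consistent, noise-free data; with noise
  the Gerchberg constraint set is infeasible and the unregularized limit
  inherits its noise sensitivity — which is the motivation for the TV and
  low-rank terms.

## A minimal session

```{r example, eval = FALSE}
p <- makePhantom(c(48L, 48L, 48L), style = "t1like", seed = 1)
sim <- simulateAcquisition(p, beta = 4, noisePct = 1, seed = 1001)
cfg <- solverConfig(lambdaTV = 1e-2, lambdaLR = 1e-1, epsilon = 0.01,
                    maxIter = 300L, tol = 1e-6)
rec <- lrtvg(sim$spectrum, support(p), cfg)
psnrInRegion(volume(rec), truth(p), support(p))
```
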