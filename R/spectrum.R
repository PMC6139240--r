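#' @include phantom.R
NULL

## signed frequency indices for an axis of extent n, in unshifted DFT order
.signedFreq <- function(n) {
  k <- 0:(n - 1L)
  ifelse(k > n / 2, k - n, k)
}

## real frequency response of the slice kernel at signed frequencies `sk`
## on a grid of extent n: the kernel DFT re-phased to the block centre
## (offset (beta-1)/2), which is exactly real for symmetric-about-centre
## kernels (Dirichlet kernel for the rectangular profile).
.profileResponse1d <- function(profile, beta, n) {
  kernel <- .sliceKernel(profile, as.integer(beta))
  sk <- .signedFreq(n)
  resp <- vapply(sk, function(k) {
    w <- sum(kernel$weights * exp(2i * pi * k * kernel$offsets / n))
    Re(w * exp(-1i * pi * k * (beta - 1) / n))
  }, numeric(1))
  resp
}

#' Frequency response of the slice profile on the high-resolution grid
#'
#' Returns the real 3D array \eqn{P_\Xi}: the frequency response of the
#' unit-sum through-slice kernel along the through-slice axis (re-phased to
#' the block centre, hence real; the periodic-sinc/Dirichlet response for the
#' rectangular profile), broadcast over the in-plane axes. Responses of
#' several observations sharing the grid combine multiplicatively.
#'
#' @param profile \code{SliceProfile}.
#' @param axis through-slice axis.
#' @param beta integer downsampling factor.
#' @param shape integer triple, the high-resolution grid.
#' @return Real 3D array of shape \code{shape}.
#' @export
sliceProfileSpectrum <- function(profile, axis, beta, shape) {
  shape <- as.integer(shape)
  resp <- .profileResponse1d(profile, beta, shape[axis])
  perm <- c(axis, setdiff(1:3, axis))
  a <- array(resp, dim = shape[perm])  # recycles along the first dim
  aperm(a, order(perm))
}

#' Embed the spectrum of one observation on the high-resolution grid
#'
#' Computes the unitary DFT of the low-resolution volume and places its
#' coefficients on the measured band \eqn{\Omega_d} of the high-resolution
#' grid: all in-plane frequencies times the \eqn{N/\beta} lowest signed
#' frequencies along the through-slice axis (Nyquist bin excluded when
#' \eqn{N/\beta} is even, preserving conjugate symmetry). Coefficients are
#' scaled by \eqn{\sqrt{\beta}} and re-phased by the half-block shift so that
#' a noise-free \eqn{\beta = 1} observation embeds exactly as
#' \code{dft3(truth)}, and an in-band signal embeds as
#' \code{dft3(truth)} times the real slice-profile response.
#'
#' @param o \code{Observation}.
#' @param targetShape integer triple, the high-resolution grid.
#' @return List with elements \code{spectrum} (a conjugate-symmetric
#'   \code{SpectrumVolume}, zero outside the band) and \code{omega}
#'   (a \code{FrequencyMask} of the band \eqn{\Omega_d}).
#' @export
observedSpectrum <- function(o, targetShape) {
  targetShape <- as.integer(targetShape)
  axis <- o@axis
  beta <- as.integer(o@beta)
  n <- targetShape[axis]
  if (n %% beta != 0L) stop("observedSpectrum: extent not divisible by beta")
  b <- n %/% beta
  low <- .rawArray(lowres(o))
  expected <- targetShape
  expected[axis] <- b
  if (!identical(dim(low), expected))
    stop("observedSpectrum: observation shape inconsistent with target shape")

  Fy <- stats::fft(low) / sqrt(length(low))
  skLow <- .signedFreq(b)
  ## drop the unpaired low-res Nyquist bin (b even) except when beta = 1,
  ## where it is the target grid's own self-conjugate Nyquist plane
  inband <- if (beta == 1L) rep(TRUE, b) else abs(skLow) < b / 2
  phase <- exp(-1i * pi * skLow * (beta - 1) / n)

  ## move the through-slice axis first for row-wise assignment
  perm <- c(axis, setdiff(1:3, axis))
  FyP <- aperm(Fy, perm)
  E <- array(0 + 0i, dim = targetShape[perm])
  tgtRows <- (skLow %% n) + 1L
  scaled <- sqrt(beta) * FyP * phase    # phase recycles down the first axis
  E[tgtRows[inband], , ] <- scaled[inband, , , drop = FALSE]
  mask <- array(0, dim = targetShape[perm])
  mask[tgtRows[inband], , ] <- 1
  list(spectrum = SpectrumVolume(aperm(E, order(perm)), symmetric = TRUE),
       omega = FrequencyMask(aperm(mask, order(perm))))
}

#' Fuse observations into the observed spectrum and frequency mask
#'
#' Embeds every observation on the high-resolution grid, deconvolves each by
#' its own slice-profile response, and averages the deconvolved coefficients
#' wherever several bands overlap. Indices where a covering observation's
#' profile response falls below 0.05 in magnitude are removed from that
#' observation's band rather than amplified, bounding the noise gain of the
#' element-wise division.
#'
#' @param observations list of \code{Observation} of the same scene.
#' @param targetShape integer triple, the high-resolution grid.
#' @param profileFloor indices whose profile response magnitude falls below
#'   this value are dropped from the band instead of deconvolved.
#' @return An \code{AssembledSpectrum}.
#' @export
assembleSpectrum <- function(observations, targetShape,
                             profileFloor = 0.05) {
  if (length(observations) < 1L) stop("assembleSpectrum: need at least one observation")
  targetShape <- as.integer(targetShape)
  acc <- array(0 + 0i, targetShape)
  count <- array(0, targetShape)
  prodResp <- array(1, targetShape)
  for (o in observations) {
    emb <- observedSpectrum(o, targetShape)
    resp <- sliceProfileSpectrum(o@profile, o@axis, o@beta, targetShape)
    prodResp <- prodResp * resp
    valid <- emb$omega@.Data == 1 & abs(resp) >= profileFloor
    dec <- array(0 + 0i, targetShape)
    dec[valid] <- emb$spectrum@.Data[valid] / resp[valid]
    acc <- acc + dec
    count <- count + valid
  }
  omega <- count > 0
  f0p <- array(0 + 0i, targetShape)
  f0p[omega] <- acc[omega] / count[omega]
  new("AssembledSpectrum",
      f0prime = SpectrumVolume(f0p, symmetric = TRUE),
      omega = FrequencyMask(array(as.numeric(omega), targetShape)),
      profileSpectrum = prodResp)
}

#' Simulate the standard two-view acquisition of a phantom
#'
#' Convenience wrapper producing the canonical experimental inputs: two
#' observations of the same phantom with mutually orthogonal through-slice
#' axes (axis 3 and axis 2), plus their assembled spectrum.
#'
#' @param p \code{Phantom}.
#' @param beta integer downsampling factor.
#' @param noisePct Gaussian noise level (percent of the truth maximum).
#' @param profile \code{SliceProfile}.
#' @param seed seed controlling the noise draws.
#' @return List with \code{observations} (list of two) and \code{spectrum}
#'   (\code{AssembledSpectrum}).
#' @export
simulateAcquisition <- function(p, beta, noisePct = 0,
                                profile = SliceProfile("rectangular"),
                                seed = 1L) {
  shape <- dim(truth(p))
  obs <- list(
    degrade(p, axis = 3L, beta = beta, noisePct = noisePct, profile = profile,
            seed = seed),
    degrade(p, axis = 2L, beta = beta, noisePct = noisePct, profile = profile,
            seed = seed + 1L)
  )
  list(observations = obs, spectrum = assembleSpectrum(obs, shape))
}
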