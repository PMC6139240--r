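#' @import methods
NULL

.isBinary <- function(x) all(x == 0 | x == 1)

#' Real 3D intensity volume
#'
#' Thin S4 wrapper around a numeric 3D \code{array} representing a scalar
#' image on an \eqn{N_1 \times N_2 \times N_3} voxel grid. All values must be
#' finite.
#'
#' @slot .Data numeric 3D array.
#' @export
setClass("IntensityVolume", contains = "array", validity = function(object) {
  if (!is.numeric(object@.Data)) return("intensity data must be numeric")
  if (length(dim(object@.Data)) != 3L) return("intensity data must be a 3D array")
  if (!all(is.finite(object@.Data))) return("intensity data must be finite")
  TRUE
})

#' Construct an IntensityVolume
#'
#' @param data numeric 3D array (or an object coercible to one).
#' @return An \code{IntensityVolume}.
#' @export
IntensityVolume <- function(data) {
  if (is(data, "IntensityVolume")) return(data)
  new("IntensityVolume", as.array(data))
}

#' Complex 3D spectrum volume
#'
#' Complex array of 3D DFT coefficients in unshifted (DC-first) order. The
#' \code{symmetric} slot asserts conjugate symmetry, i.e. the spectrum of a
#' real-valued image: the coefficient at index \code{k} equals the complex
#' conjugate of the coefficient at the negated (mod-N) index.
#'
#' @slot .Data complex 3D array.
#' @slot symmetric logical flag asserting conjugate symmetry.
#' @export
setClass("SpectrumVolume", contains = "array",
  representation(symmetric = "logical"),
  prototype(symmetric = FALSE),
  validity = function(object) {
    if (!is.complex(object@.Data)) return("spectrum data must be complex")
    if (length(dim(object@.Data)) != 3L) return("spectrum data must be a 3D array")
    if (!all(is.finite(Re(object@.Data)) & is.finite(Im(object@.Data))))
      return("spectrum data must be finite")
    if (length(object@symmetric) != 1L) return("symmetric must be a single flag")
    if (isTRUE(object@symmetric)) {
      err <- .conjSymmetryError(object@.Data)
      if (err > 1e-10) return(sprintf(
        "spectrum flagged symmetric violates conjugate symmetry (rel. error %.3g)", err))
    }
    TRUE
  })

## relative deviation from conjugate symmetry of a complex 3D array
.conjSymmetryError <- function(a) {
  nrm <- sqrt(sum(Mod(a)^2))
  if (nrm == 0) return(0)
  sqrt(sum(Mod(a - Conj(.reflectIndex(a)))^2)) / nrm
}

## a[k] -> a[-k mod N] along every axis
.reflectIndex <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) if (n == 1L) 1L else c(1L, n:2L))
  do.call(`[`, c(list(a), idx))
}

#' Construct a SpectrumVolume
#'
#' @param data complex 3D array.
#' @param symmetric assert conjugate symmetry (validated to 1e-10 relative).
#' @return A \code{SpectrumVolume}.
#' @export
SpectrumVolume <- function(data, symmetric = FALSE) {
  new("SpectrumVolume", as.array(data), symmetric = symmetric)
}

#' Binary object-support mask in image space
#'
#' Values are 0 (background, outside the object boundary) or 1 (object).
#' The complement mask is \code{1 - mask}.
#'
#' @export
setClass("RegionMask", contains = "array", validity = function(object) {
  if (length(dim(object@.Data)) != 3L) return("mask must be a 3D array")
  if (!.isBinary(object@.Data)) return("mask values must be 0 or 1")
  TRUE
})

#' @rdname RegionMask-class
#' @param data binary (0/1) 3D array.
#' @export
RegionMask <- function(data) {
  if (is(data, "RegionMask")) return(data)
  new("RegionMask", array(as.numeric(data), dim(as.array(data))))
}

#' Binary measured-frequency mask in spectrum space
#'
#' Marks the measured region of 3D frequency space (1 = measured). The index
#' set must be conjugate-symmetric so it can mask spectra of real images.
#'
#' @export
setClass("FrequencyMask", contains = "array", validity = function(object) {
  if (length(dim(object@.Data)) != 3L) return("mask must be a 3D array")
  if (!.isBinary(object@.Data)) return("mask values must be 0 or 1")
  if (!all(object@.Data == .reflectIndex(object@.Data)))
    return("frequency mask index set must be conjugate-symmetric")
  TRUE
})

#' @rdname FrequencyMask-class
#' @param data binary (0/1) 3D array, conjugate-symmetric as an index set.
#' @export
FrequencyMask <- function(data) {
  if (is(data, "FrequencyMask")) return(data)
  new("FrequencyMask", array(as.numeric(data), dim(as.array(data))))
}

#' Tensor trace-norm mode weights
#'
#' Nonnegative weights over the three unfolding modes, summing to one.
#' The default is uniform (1/3, 1/3, 1/3).
#'
#' @slot weights numeric triple.
#' @export
setClass("ModeWeights", representation(weights = "numeric"),
  prototype(weights = rep(1 / 3, 3)),
  validity = function(object) {
    w <- object@weights
    if (length(w) != 3L) return("three mode weights required")
    if (any(w < 0)) return("mode weights must be nonnegative")
    if (abs(sum(w) - 1) > 1e-10) return("mode weights must sum to 1")
    TRUE
  })

#' @rdname ModeWeights-class
#' @param weights nonnegative numeric triple summing to 1.
#' @export
ModeWeights <- function(weights = rep(1 / 3, 3)) new("ModeWeights", weights = weights)

#' Slice-selection profile descriptor
#'
#' Describes the through-slice excitation kernel of one acquisition:
#' \code{"rectangular"} (length-\eqn{\beta} boxcar average, the ideal
#' slice-select profile) or \code{"gaussian"} (discretized Gaussian whose
#' full width at half maximum is \code{width} times \eqn{\beta} voxels).
#'
#' @slot kind character, "rectangular" or "gaussian".
#' @slot width numeric FWHM multiplier (relative to \eqn{\beta}); ignored for
#'   rectangular profiles.
#' @export
setClass("SliceProfile", representation(kind = "character", width = "numeric"),
  prototype(kind = "rectangular", width = 1),
  validity = function(object) {
    if (!object@kind %in% c("rectangular", "gaussian"))
      return("profile kind must be 'rectangular' or 'gaussian'")
    if (object@width <= 0) return("profile width must be positive")
    TRUE
  })

#' @rdname SliceProfile-class
#' @param kind profile kind.
#' @param width FWHM multiplier relative to beta (gaussian only).
#' @export
SliceProfile <- function(kind = c("rectangular", "gaussian"), width = 1) {
  new("SliceProfile", kind = match.arg(kind), width = width)
}

#' Synthetic ground-truth phantom
#'
#' An isotropic, noise-free piecewise-constant test volume together with its
#' object-support mask. The truth is exactly zero outside the support, and
#' the support keeps a margin of at least two voxels from the grid boundary.
#'
#' @slot truth IntensityVolume, the ideal isotropic image.
#' @slot support RegionMask, the object region.
#' @slot seed integer seed the phantom was generated from.
#' @export
setClass("Phantom",
  representation(truth = "IntensityVolume", support = "RegionMask", seed = "integer"),
  validity = function(object) {
    if (!identical(dim(object@truth), dim(object@support)))
      return("truth and support must share a grid")
    if (any(object@truth[object@support@.Data == 0] != 0))
      return("truth must vanish outside the support")
    TRUE
  })

#' One anisotropic low-resolution observation
#'
#' A measured volume whose through-slice axis has \eqn{\beta} times fewer
#' samples than the target high-resolution grid, produced by slice-profile
#' blurring, downsampling, and additive Gaussian noise.
#'
#' @slot lowres IntensityVolume on the anisotropic grid.
#' @slot axis integer in 1:3, the through-slice axis.
#' @slot beta integer scale factor (>= 1).
#' @slot noisePct numeric noise level as a percentage of the truth maximum.
#' @slot profile SliceProfile used in the degradation.
#' @export
setClass("Observation",
  representation(lowres = "IntensityVolume", axis = "integer", beta = "integer",
                 noisePct = "numeric", profile = "SliceProfile"),
  validity = function(object) {
    if (!object@axis %in% 1:3) return("axis must be 1, 2 or 3")
    if (object@beta < 1L) return("beta must be >= 1")
    if (object@noisePct < 0) return("noisePct must be nonnegative")
    TRUE
  })

#' Assembled observed spectrum on the high-resolution grid
#'
#' The fused, slice-profile-deconvolved observed spectrum F0' together with
#' the measured-frequency mask and the (multiplicatively combined) profile
#' frequency response. F0' is zero outside the mask and conjugate-symmetric.
#'
#' @slot f0prime SpectrumVolume, deconvolved observed coefficients.
#' @slot omega FrequencyMask of measured indices.
#' @slot profileSpectrum real 3D array, combined slice-profile response.
#' @export
setClass("AssembledSpectrum",
  representation(f0prime = "SpectrumVolume", omega = "FrequencyMask",
                 profileSpectrum = "array"),
  validity = function(object) {
    if (!identical(dim(object@f0prime), dim(object@omega)))
      return("spectrum and mask must share a grid")
    if (any(Mod(object@f0prime@.Data[object@omega@.Data == 0]) > 0))
      return("f0prime must vanish outside omega")
    TRUE
  })

#' ADMM solver configuration
#'
#' Hyperparameters of the spectrum-fitting reconstruction. \code{lambdaTV}
#' and \code{lambdaLR} weight the total-variation and tensor trace-norm
#' priors; \code{epsilon} couples the low-rank slack variables to the image
#' (default 0.01); \code{rho} is the ADMM penalty weight. Setting
#' \code{lambdaTV = lambdaLR = 0} recovers the Gerchberg limit, and
#' \code{lambdaLR = epsilon = 0} the TV-plus-boundary configuration.
#'
#' @export
setClass("SolverConfig",
  representation(lambdaTV = "numeric", lambdaLR = "numeric", epsilon = "numeric",
                 rho = "numeric", maxIter = "integer", tol = "numeric",
                 cgMaxIter = "integer", cgTol = "numeric",
                 modeWeights = "ModeWeights"),
  validity = function(object) {
    if (object@lambdaTV < 0 || object@lambdaLR < 0 || object@epsilon < 0)
      return("lambdaTV, lambdaLR and epsilon must be nonnegative")
    if (object@rho <= 0) return("rho must be positive")
    if (object@tol <= 0) return("tol must be positive")
    if (object@maxIter < 1L || object@cgMaxIter < 1L)
      return("iteration limits must be >= 1")
    if (object@lambdaLR > 0 && object@epsilon == 0)
      return("epsilon must be positive when lambdaLR > 0 (slack coupling)")
    TRUE
  })

#' @rdname SolverConfig-class
#' @param lambdaTV,lambdaLR,epsilon,rho,tol,cgTol numeric hyperparameters.
#' @param maxIter,cgMaxIter iteration limits.
#' @param modeWeights ModeWeights for the tensor trace norm.
#' @export
solverConfig <- function(lambdaTV = 0, lambdaLR = 0, epsilon = 0.01, rho = 1,
                         maxIter = 500L, tol = 1e-7, cgMaxIter = 30L,
                         cgTol = 1e-4, modeWeights = ModeWeights()) {
  new("SolverConfig", lambdaTV = lambdaTV, lambdaLR = lambdaLR,
      epsilon = epsilon, rho = rho, maxIter = as.integer(maxIter), tol = tol,
      cgMaxIter = as.integer(cgMaxIter), cgTol = cgTol, modeWeights = modeWeights)
}

#' Result of the Gerchberg POCS iteration
#'
#' @slot volume reconstructed IntensityVolume (support holds exactly).
#' @slot iterations number of iterations performed.
#' @slot residualHistory relative change of the image per iteration.
#' @export
setClass("PocsResult",
  representation(volume = "IntensityVolume", iterations = "integer",
                 residualHistory = "numeric"))

#' Result of an ADMM reconstruction
#'
#' @slot volume reconstructed IntensityVolume (hard support projection applied).
#' @slot iterations iterations performed.
#' @slot costHistory objective value per iteration.
#' @slot residualHistory matrix of per-iteration constraint residuals
#'   (columns: tv split, spectrum consensus, support).
#' @slot converged logical, whether the stopping tolerance was reached.
#' @slot diagnostics list of solver internals (final residuals, config echo).
#' @export
setClass("SolverResult",
  representation(volume = "IntensityVolume", iterations = "integer",
                 costHistory = "numeric", residualHistory = "matrix",
                 converged = "logical", diagnostics = "list"))

## ---- show methods ----

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object)
  cat(sprintf("IntensityVolume %dx%dx%d, range [%.4g, %.4g]\n",
              d[1], d[2], d[3], min(object@.Data), max(object@.Data)))
})

setMethod("show", "SpectrumVolume", function(object) {
  d <- dim(object)
  cat(sprintf("SpectrumVolume %dx%dx%d, energy %.4g, symmetric=%s\n",
              d[1], d[2], d[3], sum(Mod(object@.Data)^2), object@symmetric))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@truth)
  cat(sprintf("Phantom %dx%dx%d, support %d voxels (%.1f%%), seed %d\n",
              d[1], d[2], d[3], sum(object@support@.Data),
              100 * mean(object@support@.Data), object@seed))
})

setMethod("show", "Observation", function(object) {
  d <- dim(object@lowres)
  cat(sprintf("Observation %dx%dx%d, through-slice axis %d, beta %d, noise %.3g%%, %s profile\n",
              d[1], d[2], d[3], object@axis, object@beta, object@noisePct,
              object@profile@kind))
})

setMethod("show", "AssembledSpectrum", function(object) {
  d <- dim(object@f0prime)
  cat(sprintf("AssembledSpectrum %dx%dx%d, measured fraction %.3f\n",
              d[1], d[2], d[3], mean(object@omega@.Data)))
})

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf(paste0("SolverConfig: lambdaTV=%.3g lambdaLR=%.3g epsilon=%.3g ",
                     "rho=%.3g maxIter=%d tol=%.1e\n"),
              object@lambdaTV, object@lambdaLR, object@epsilon, object@rho,
              object@maxIter, object@tol))
})

setMethod("show", "PocsResult", function(object) {
  cat(sprintf("PocsResult: %d iterations, final change %.3g\n",
              object@iterations, utils::tail(object@residualHistory, 1)))
})

setMethod("show", "SolverResult", function(object) {
  cat(sprintf("SolverResult: %d iterations, converged=%s, final cost %.6g\n",
              object@iterations, object@converged,
              utils::tail(object@costHistory, 1)))
})
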