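#' @include evaluation.R
NULL

#' Read and write 3D volumes as NIfTI-1
#'
#' Volumes round-trip losslessly at 64-bit float. \code{pixdim} records the
#' voxel size (mm); low-resolution observations written by the simulator
#' carry their \eqn{\beta} mm slice spacing on the through-slice axis.
#'
#' @param path file path (.nii or .nii.gz).
#' @return \code{readVolume}: an \code{IntensityVolume} with a
#'   \code{"pixdim"} attribute.
#' @export
readVolume <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("readVolume: expected a 3D image, got %dD (%s)",
                 length(d), paste(d, collapse = "x")))
  out <- IntensityVolume(array(as.numeric(img), d))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' @rdname readVolume
#' @param v \code{IntensityVolume} (or 3D array).
#' @param pixdim numeric triple of voxel sizes in mm.
#' @export
writeVolume <- function(v, path, pixdim = c(1, 1, 1)) {
  a <- .rawArray(v)
  attr(a, "pixdim") <- pixdim
  img <- RNifti::asNifti(a, internal = FALSE, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary region mask from NIfTI
#'
#' @param path NIfTI file; values must be exactly 0 or 1.
#' @param type "region" (image space) or "frequency" (spectrum space).
#' @return A \code{RegionMask} or \code{FrequencyMask}.
#' @export
readMask <- function(path, type = c("region", "frequency")) {
  type <- match.arg(type)
  v <- readVolume(path)
  a <- .rawArray(v)
  if (!all(a == 0 | a == 1))
    stop("readMask: mask file contains values other than 0/1")
  if (type == "region") RegionMask(a) else FrequencyMask(a)
}

#' Read and write an assembled spectrum as a NIfTI triple
#'
#' The complex observed spectrum is serialized as two real NIfTI volumes
#' (real and imaginary parts) plus the binary frequency mask. Conjugate
#' symmetry is validated on read; a violation above 1e-6 relative raises a
#' warning.
#'
#' @param realPath,imagPath,maskPath file paths of the triple.
#' @return \code{readSpectrum}: an \code{AssembledSpectrum} (with a flat
#'   unit profile response, the profile having been divided out on
#'   assembly).
#' @export
readSpectrum <- function(realPath, imagPath, maskPath) {
  re <- .rawArray(readVolume(realPath))
  im <- .rawArray(readVolume(imagPath))
  if (!identical(dim(re), dim(im)))
    stop("readSpectrum: real/imaginary shapes differ")
  mask <- readMask(maskPath, type = "frequency")
  if (!identical(dim(re), dim(.rawArray(mask))))
    stop("readSpectrum: mask shape differs from spectrum shape")
  a <- complex(real = re, imaginary = im)
  dim(a) <- dim(re)
  err <- .conjSymmetryError(a)
  symmetric <- err <= 1e-6
  if (!symmetric)
    warning(sprintf("readSpectrum: conjugate symmetry violated (rel. error %.3g)", err))
  new("AssembledSpectrum",
      f0prime = SpectrumVolume(a * .rawArray(mask), symmetric = symmetric),
      omega = mask, profileSpectrum = array(1, dim(re)))
}

#' @rdname readSpectrum
#' @param s \code{AssembledSpectrum}.
#' @export
writeSpectrum <- function(s, realPath, imagPath, maskPath) {
  a <- .rawArray(f0prime(s))
  writeVolume(Re(a), realPath)
  writeVolume(Im(a), imagPath)
  writeVolume(.rawArray(omegaMask(s)), maskPath)
  invisible(c(realPath, imagPath, maskPath))
}
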