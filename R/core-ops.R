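#' @include AllClasses.R
NULL

## raw array out of a wrapper class (keeps internal math on plain arrays)
.rawArray <- function(x) {
  if (isS4(x)) x@.Data else as.array(x)
}

#' Unitary 3D discrete Fourier transform
#'
#' Orthonormal (\eqn{1/\sqrt{N}} both ways) 3D DFT, so that the adjoint of
#' \code{dft3} equals its inverse and Parseval's identity holds exactly.
#' Coefficients are in unshifted order (DC at index \code{[1,1,1]}).
#'
#' @param v an \code{IntensityVolume} or real 3D array.
#' @return A \code{SpectrumVolume} flagged conjugate-symmetric.
#' @seealso [idft3()]
#' @export
dft3 <- function(v) {
  a <- .rawArray(v)
  if (!all(is.finite(a))) stop("dft3: input must be finite")
  SpectrumVolume(stats::fft(a) / sqrt(length(a)), symmetric = TRUE)
}

#' Inverse unitary 3D discrete Fourier transform
#'
#' Exact inverse of [dft3()]. When the input is conjugate-symmetric the
#' (numerically zero) imaginary part is discarded; otherwise the real part is
#' returned and the relative magnitude of the discarded imaginary part is
#' attached as the \code{"imagDropped"} attribute.
#'
#' @param s a \code{SpectrumVolume} or complex 3D array.
#' @return An \code{IntensityVolume}.
#' @export
idft3 <- function(s) {
  a <- .rawArray(s)
  if (!all(is.finite(Re(a)) & is.finite(Im(a)))) stop("idft3: input must be finite")
  z <- stats::fft(a, inverse = TRUE) / sqrt(length(a))
  out <- IntensityVolume(Re(z))
  symmetric <- if (is(s, "SpectrumVolume")) s@symmetric else FALSE
  if (!symmetric) {
    nrm <- sqrt(sum(Re(z)^2))
    imag <- sqrt(sum(Im(z)^2)) / max(nrm, .Machine$double.eps)
    attr(out, "imagDropped") <- imag
  }
  out
}

## complex idft without discarding the imaginary part (internal)
.idft3c <- function(a) stats::fft(a, inverse = TRUE) / sqrt(length(a))

## circular shift of a 3D array along one axis by `by` (positive = pull from
## the right, i.e. result[i] = a[i + by] with wraparound)
.shift3 <- function(a, axis, by = 1L) {
  n <- dim(a)[axis]
  by <- ((by %% n) + n) %% n
  if (by == 0L) return(a)
  ord <- c((by + 1L):n, seq_len(by))
  switch(axis,
         a[ord, , , drop = FALSE],
         a[, ord, , drop = FALSE],
         a[, , ord, drop = FALSE])
}

#' Forward finite difference with periodic boundary
#'
#' First-order forward difference along one axis with circular wraparound,
#' \eqn{(\nabla_d X)_i = X_{i+1} - X_i}. This is the matrix \eqn{L_d} of the
#' TV splitting; periodicity makes \eqn{L_d^T L_d} circulant so it
#' diagonalizes under the DFT.
#'
#' @param v \code{IntensityVolume} or real 3D array.
#' @param axis 1, 2 or 3.
#' @return \code{IntensityVolume} of differences.
#' @export
forwardDiff <- function(v, axis) {
  if (!(length(axis) == 1L && axis %in% 1:3)) stop("forwardDiff: axis must be 1, 2 or 3")
  a <- .rawArray(v)
  IntensityVolume(.shift3(a, axis, 1L) - a)
}

## adjoint of forwardDiff: (L^T y)_i = y_{i-1} - y_i (periodic)
.diffAdj <- function(a, axis) .shift3(a, axis, -1L) - a

## gradient field Lx as a list of three arrays
.applyL <- function(a) lapply(1:3, function(d) .shift3(a, d, 1L) - a)

## adjoint L^T applied to a 3-list
.applyLt <- function(g) {
  .diffAdj(g[[1]], 1L) + .diffAdj(g[[2]], 2L) + .diffAdj(g[[3]], 3L)
}

#' Isotropic total variation of a 3D volume
#'
#' Sum over voxels of the Euclidean norm of the forward-difference gradient,
#' \eqn{\sum_{s,t,u} \sqrt{\sum_{d=1}^3 (\nabla_d X)^2_{stu}}}, with periodic
#' boundary differences.
#'
#' @param v \code{IntensityVolume} or real 3D array.
#' @return Nonnegative scalar.
#' @export
totalVariation <- function(v) {
  g <- .applyL(.rawArray(v))
  sum(sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2))
}

#' Mode-i unfolding of a 3D tensor
#'
#' Rearranges a 3D array into a matrix whose rows are indexed by mode
#' \code{mode} and whose columns run over the remaining modes.
#' [foldTensor()] is the exact inverse.
#'
#' @param t 3D real array (or \code{IntensityVolume}).
#' @param mode 1, 2 or 3.
#' @return A matrix with \code{dim(t)[mode]} rows.
#' @export
unfoldTensor <- function(t, mode) {
  if (!(length(mode) == 1L && mode %in% 1:3)) stop("unfoldTensor: mode must be 1, 2 or 3")
  a <- .rawArray(t)
  d <- dim(a)
  perm <- c(mode, setdiff(1:3, mode))
  m <- aperm(a, perm)
  dim(m) <- c(d[mode], prod(d[-mode]))
  m
}

#' @rdname unfoldTensor
#' @param m matrix produced by \code{unfoldTensor}.
#' @param shape integer triple, the original tensor extents.
#' @export
foldTensor <- function(m, mode, shape) {
  if (!(length(mode) == 1L && mode %in% 1:3)) stop("foldTensor: mode must be 1, 2 or 3")
  shape <- as.integer(shape)
  if (length(shape) != 3L || nrow(m) != shape[mode] || ncol(m) != prod(shape[-mode]))
    stop("foldTensor: matrix extent inconsistent with shape/mode")
  perm <- c(mode, setdiff(1:3, mode))
  a <- array(m, dim = shape[perm])
  aperm(a, order(perm))
}

#' Singular value soft-thresholding
#'
#' Replaces each singular value \eqn{\sigma} of a real matrix by
#' \eqn{\max(\sigma - \tau, 0)} while keeping the singular vectors: the
#' proximal operator of \eqn{\tau\,\|\cdot\|_*} (nuclear norm).
#' \code{method = "gram"} computes the thresholding through an eigendecomposition
#' of the smaller Gram matrix, which is much faster for very fat or tall
#' matrices and is used inside the solvers.
#'
#' @param m real matrix.
#' @param tau nonnegative threshold.
#' @param method "svd" (LAPACK SVD) or "gram" (Gram-matrix eigendecomposition).
#' @return Matrix of the same shape.
#' @export
svt <- function(m, tau, method = c("svd", "gram")) {
  if (is.complex(m)) stop("svt: complex matrices are not supported")
  if (tau < 0) stop("svt: tau must be nonnegative")
  method <- match.arg(method)
  if (tau == 0) return(m)
  if (method == "svd") {
    s <- svd(m)
    d <- pmax(s$d - tau, 0)
    keep <- d > 0
    if (!any(keep)) return(matrix(0, nrow(m), ncol(m)))
    return(s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE])))
  }
  ## gram path: work on the smaller side
  if (nrow(m) <= ncol(m)) {
    G <- tcrossprod(m)
    e <- eigen(G, symmetric = TRUE)
    sig <- sqrt(pmax(e$values, 0))
    scale <- ifelse(sig > tau, (sig - tau) / pmax(sig, .Machine$double.eps), 0)
    e$vectors %*% (scale * crossprod(e$vectors, m))
  } else {
    t(svt(t(m), tau, method = "gram"))
  }
}

#' Weighted tensor trace norm
#'
#' \eqn{\sum_i \alpha_i \|\mathrm{unfold}_i(X)\|_*}: the weighted sum of the
#' nuclear norms of the three mode unfoldings, a convex surrogate for
#' multilinear rank.
#'
#' @param t 3D real array.
#' @param w \code{ModeWeights} (defaults to uniform 1/3).
#' @return Nonnegative scalar.
#' @export
tensorTraceNorm <- function(t, w = ModeWeights()) {
  if (!is(w, "ModeWeights")) w <- ModeWeights(w)
  a <- .rawArray(t)
  sum(vapply(1:3, function(i) {
    w@weights[i] * sum(svd(unfoldTensor(a, i), nu = 0, nv = 0)$d)
  }, numeric(1)))
}

## nuclear norm via gram eigenvalues (fast path for solver diagnostics)
.nuclearNormGram <- function(m) {
  G <- if (nrow(m) <= ncol(m)) tcrossprod(m) else crossprod(m)
  sum(sqrt(pmax(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 0)))
}

#' Group (vectorial) soft-thresholding
#'
#' Per-voxel shrinkage of a 3-vector field:
#' \eqn{w_s \mapsto \max(1 - \kappa/\|w_s\|_2,\, 0)\, w_s} (zero when
#' \eqn{\|w_s\|_2 = 0}). This is the proximal operator of
#' \eqn{\kappa \|\cdot\|_{1,2}} and performs the TV shrinkage step.
#'
#' @param g list of three equally shaped real arrays (the per-voxel vector
#'   components).
#' @param kappa nonnegative threshold.
#' @return List of three arrays, same shapes.
#' @export
groupSoftThreshold <- function(g, kappa) {
  if (kappa < 0) stop("groupSoftThreshold: kappa must be nonnegative")
  if (kappa == 0) return(g)
  nrm <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  scale <- ifelse(nrm > kappa, 1 - kappa / pmax(nrm, .Machine$double.eps), 0)
  lapply(g, function(a) scale * a)
}
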