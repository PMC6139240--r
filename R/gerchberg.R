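#' @include spectrum.R
NULL

#' Gerchberg POCS super-resolution
#'
#' Alternating projection onto two convex sets: (I) image support --- the
#' image is zeroed outside the object region \eqn{\Gamma}; (II) spectrum
#' fidelity --- DFT coefficients on the measured region \eqn{\Omega} are
#' reset to their observed values. Starting from \eqn{F = F_0}, the iteration
#' is \eqn{X \leftarrow P_\Gamma \circ \mathrm{IDFT}(F)},
#' \eqn{F \leftarrow P_\Omega \circ F_0 + P_{\bar\Omega} \circ \mathrm{DFT}(X)},
#' stopped when the relative L2 change of \eqn{X} drops below \code{tol}.
#'
#' @param f0 observed spectrum: a \code{SpectrumVolume} (zero outside
#'   \code{omega}) or an \code{AssembledSpectrum} (in which case \code{omega}
#'   is taken from it).
#' @param omega \code{FrequencyMask}; ignored when \code{f0} is an
#'   \code{AssembledSpectrum}.
#' @param gamma \code{RegionMask}, the object support.
#' @param maxIter iteration cap.
#' @param tol relative-change stopping tolerance.
#' @return A \code{PocsResult}; the returned volume satisfies the support
#'   constraint exactly by construction.
#' @export
gerchberg <- function(f0, omega = NULL, gamma, maxIter = 2000L, tol = 1e-7) {
  if (is(f0, "AssembledSpectrum")) {
    omega <- omegaMask(f0)
    f0 <- f0prime(f0)
  }
  if (is.null(omega)) stop("gerchberg: omega mask required")
  F0 <- .rawArray(f0)
  pOm <- .rawArray(omega)
  pG <- .rawArray(gamma)
  if (any(Mod(F0[pOm == 0]) > 0)) stop("gerchberg: f0 must be zero outside omega")
  Fk <- F0
  n <- length(F0)
  Xold <- NULL
  hist <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    X <- pG * Re(stats::fft(Fk, inverse = TRUE) / sqrt(n))
    Fk <- pOm * F0 + (1 - pOm) * (stats::fft(X) / sqrt(n))
    if (!is.null(Xold)) {
      change <- sqrt(sum((X - Xold)^2)) / max(sqrt(sum(Xold^2)), .Machine$double.eps)
      hist <- c(hist, change)
      if (change < tol || iter >= maxIter) {
        Xold <- X
        break
      }
    } else {
      hist <- c(hist, NA_real_)
    }
    Xold <- X
    if (iter >= maxIter) break
  }
  new("PocsResult", volume = IntensityVolume(Xold), iterations = iter,
      residualHistory = hist)
}
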