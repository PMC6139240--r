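#' @include lrtvg.R
NULL

## forward model A_d of one observation (blur + block-aligned decimation)
## and its adjoint; linear, noise-free
.forwardModel <- function(o, fullShape) {
  kernel <- .sliceKernel(o@profile, o@beta)
  axis <- o@axis
  beta <- o@beta
  list(
    apply = function(x) .blurDecimate(x, axis, beta, kernel),
    adjoint = function(y) .blurDecimateAdj(y, axis, beta, kernel, fullShape)
  )
}

.checkObsList <- function(obs) {
  if (length(obs) < 1L) stop("at least one observation required")
  if (!all(vapply(obs, function(o) is(o, "Observation"), logical(1))))
    stop("observations must be Observation objects")
}

## replicate each slice beta times along the through-slice axis
.replicateAxis <- function(a, axis, beta) {
  if (beta == 1L) return(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  rep_idx <- rep(seq_len(d[1]), each = beta)
  out <- ap[rep_idx, , , drop = FALSE]
  aperm(out, order(perm))
}

#' Nearest-neighbour upsampling baseline
#'
#' Replicates each slice of every observation \eqn{\beta} times along its
#' through-slice axis; several observations are fused by voxel-wise
#' averaging.
#'
#' @param obs list of \code{Observation}.
#' @param targetShape integer triple.
#' @return \code{IntensityVolume}.
#' @export
nnUpsample <- function(obs, targetShape) {
  .checkObsList(obs)
  targetShape <- as.integer(targetShape)
  acc <- array(0, targetShape)
  for (o in obs) {
    up <- .replicateAxis(.rawArray(lowres(o)), o@axis, o@beta)
    if (!identical(dim(up), targetShape)) stop("nnUpsample: shape mismatch")
    acc <- acc + up
  }
  IntensityVolume(acc / length(obs))
}

#' Cubic-spline upsampling baseline
#'
#' Interpolates each observation along its through-slice axis with a natural
#' cubic spline through the block-centre sample positions (offset
#' \eqn{(\beta-1)/2}, consistent with the block-mean degradation), evaluated
#' at every high-resolution voxel; observations are averaged.
#'
#' @inheritParams nnUpsample
#' @return \code{IntensityVolume}.
#' @export
bicubicUpsample <- function(obs, targetShape) {
  .checkObsList(obs)
  targetShape <- as.integer(targetShape)
  acc <- array(0, targetShape)
  for (o in obs) {
    beta <- o@beta
    axis <- o@axis
    a <- .rawArray(lowres(o))
    if (beta == 1L) {
      acc <- acc + a
      next
    }
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    centres <- (seq_len(d[1]) - 1) * beta + (beta + 1) / 2  # 1-based coords
    xout <- seq_len(targetShape[axis])
    up <- apply(m, 2, function(col)
      stats::spline(centres, col, xout = xout, method = "natural")$y)
    upA <- array(up, dim = c(targetShape[axis], d[2], d[3]))
    acc <- acc + aperm(upA, order(perm))
  }
  IntensityVolume(acc / length(obs))
}

#' Zero-padding (zero-filled) reconstruction
#'
#' Inverse DFT of the observed spectrum with all unmeasured coefficients set
#' to zero.
#'
#' @param data \code{AssembledSpectrum}.
#' @return \code{IntensityVolume}.
#' @export
zeroPadSR <- function(data) {
  idft3(SpectrumVolume(.rawArray(f0prime(data)) * .rawArray(omegaMask(data)),
                       symmetric = TRUE))
}

## shared ADMM machinery for the image-domain-fidelity baselines:
## minimize 1/2 sum_d ||A_d x - x0_d||^2 + lambdaTV ||x||_TV
##        (+ (lambdaLR/3) sum_i ||unfold_i(M_i)||_* with eps slack coupling)
.imageFidelityADMM <- function(obs, targetShape, cfg, lowRank) {
  .checkObsList(obs)
  targetShape <- as.integer(targetShape)
  models <- lapply(obs, .forwardModel, fullShape = targetShape)
  x0 <- lapply(obs, function(o) .rawArray(lowres(o)))
  rho <- cfg@rho
  if (lowRank && cfg@lambdaLR > 0 && cfg@epsilon == 0)
    stop("lrtvSR: epsilon must be positive when lambdaLR > 0")
  useM <- lowRank && cfg@epsilon > 0 && cfg@lambdaLR > 0
  eps <- if (useM) cfg@epsilon else 0

  Aty <- array(0, targetShape)
  for (d in seq_along(models)) Aty <- Aty + models[[d]]$adjoint(x0[[d]])

  applySys <- function(w) {
    out <- rho * .applyLt(.applyL(w)) + 3 * eps * w
    for (mo in models) out <- out + mo$adjoint(mo$apply(w))
    out
  }
  zeroes <- function() array(0, targetShape)
  ## start from the NN fusion: cheap and in the right intensity range
  x <- .rawArray(nnUpsample(obs, targetShape))
  y <- lapply(1:3, function(i) zeroes())
  z <- lapply(1:3, function(i) zeroes())
  m <- lapply(1:3, function(i) x)
  v <- lapply(1:3, function(i) zeroes())

  objective <- function(x, m, v) {
    val <- 0
    for (d in seq_along(models)) {
      val <- val + 0.5 * sum((models[[d]]$apply(x) - x0[[d]])^2)
    }
    if (cfg@lambdaTV > 0) val <- val + cfg@lambdaTV * totalVariation(x)
    if (lowRank && cfg@lambdaLR > 0) {
      val <- val + cfg@lambdaLR / 3 * sum(vapply(1:3, function(i)
        .nuclearNormGram(unfoldTensor(m[[i]], i)), numeric(1)))
    }
    if (useM) {
      for (i in 1:3) {
        val <- val + eps / 2 * (sum((x - m[[i]] + v[[i]])^2) - sum(v[[i]]^2))
      }
    }
    val
  }

  cost <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < cfg@maxIter) {
    iter <- iter + 1L
    ## x block by CG
    b <- Aty + .applyLt(z) + rho * .applyLt(y)
    if (useM) for (i in 1:3) b <- b + eps * (m[[i]] - v[[i]])
    r <- b - applySys(x)
    p <- r
    rs <- sum(r^2)
    bn <- max(sqrt(sum(b^2)), .Machine$double.eps)
    cgIt <- 0L
    while (sqrt(rs) / bn > cfg@cgTol && cgIt < cfg@cgMaxIter) {
      cgIt <- cgIt + 1L
      Ap <- applySys(p)
      al <- rs / sum(p * Ap)
      x <- x + al * p
      r <- r - al * Ap
      rsN <- sum(r^2)
      p <- r + (rsN / rs) * p
      rs <- rsN
    }
    ## y block
    Lx <- .applyL(x)
    w <- lapply(1:3, function(d) Lx[[d]] - z[[d]] / rho)
    y <- groupSoftThreshold(w, cfg@lambdaTV / rho)
    ## m block
    if (useM) {
      if (cfg@lambdaLR == 0) {
        m <- lapply(1:3, function(i) x + v[[i]])
      } else {
        tau <- cfg@lambdaLR / (3 * eps)
        m <- lapply(1:3, function(i)
          foldTensor(svt(unfoldTensor(x + v[[i]], i), tau, method = "gram"),
                     i, targetShape))
      }
      for (i in 1:3) v[[i]] <- v[[i]] + x - m[[i]]
    }
    ## duals
    for (d in 1:3) z[[d]] <- z[[d]] + rho * (y[[d]] - Lx[[d]])
    J <- objective(x, m, v)
    cost <- c(cost, J)
    if (!is.finite(J) || (length(cost) > 1 && J > 1e6 * max(cost[1], 1)))
      stop("image-fidelity ADMM diverged")
    if (length(cost) >= 2L &&
        abs(cost[length(cost)] - cost[length(cost) - 1L]) / max(abs(J), 1) < cfg@tol) {
      converged <- TRUE
      break
    }
  }
  new("SolverResult", volume = IntensityVolume(x), iterations = iter,
      costHistory = cost,
      residualHistory = matrix(NA_real_, 0, 3,
        dimnames = list(NULL, c("tvSplit", "consensus", "support"))),
      converged = converged,
      diagnostics = list(config = cfg))
}

#' Total-variation super-resolution baseline
#'
#' Minimizes \eqn{\frac12 \sum_d \|A_d x - x_{0,d}\|_2^2 +
#' \lambda_{TV}\|x\|_{TV}} over the high-resolution volume, where \eqn{A_d}
#' is the known blur-plus-decimation forward model of observation \eqn{d},
#' by ADMM with a TV split.
#'
#' @param obs list of \code{Observation}.
#' @param targetShape integer triple.
#' @param cfg \code{SolverConfig} (lambdaLR/epsilon ignored).
#' @return A \code{SolverResult}.
#' @export
tvSR <- function(obs, targetShape, cfg = solverConfig(lambdaTV = 1e-3)) {
  .imageFidelityADMM(obs, targetShape, cfg, lowRank = FALSE)
}

#' Low-rank plus total-variation super-resolution baseline
#'
#' Adds the weighted tensor trace-norm prior (through per-mode slack
#' variables with epsilon coupling) to the TV super-resolution objective;
#' the fidelity stays in the image domain.
#'
#' @inheritParams tvSR
#' @return A \code{SolverResult}.
#' @export
lrtvSR <- function(obs, targetShape,
                   cfg = solverConfig(lambdaTV = 1e-3, lambdaLR = 1e-2)) {
  .imageFidelityADMM(obs, targetShape, cfg, lowRank = TRUE)
}
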