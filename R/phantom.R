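#' @include core-ops.R
NULL

## run expr with a private RNG stream; global .Random.seed is untouched
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## voxel-center coordinate grids, one array per axis
.coordGrids <- function(shape) {
  list(
    array(rep(seq_len(shape[1]), times = shape[2] * shape[3]), shape),
    array(rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]), shape),
    array(rep(seq_len(shape[3]), each = shape[1] * shape[2]), shape)
  )
}

.ellipsoidMask <- function(grids, center, semi) {
  q <- ((grids[[1]] - center[1]) / semi[1])^2 +
       ((grids[[2]] - center[2]) / semi[2])^2 +
       ((grids[[3]] - center[3]) / semi[3])^2
  q <= 1
}

#' Generate a synthetic piecewise-constant head phantom
#'
#' Builds a deterministic nested-ellipsoid phantom emulating the contrast
#' structure of a T1- or T2-weighted head image: an outer shell (the object
#' support), a middle "parenchyma" shell, and an inner "fluid" core, with
#' contrast ordering inverted between the two styles. Optional lesions are
#' small spherical blobs inside the middle shell. The support keeps a margin
#' of at least two voxels from every grid face, and the truth is exactly zero
#' outside the support.
#'
#' @param shape integer triple, each extent >= 16.
#' @param style "t1like" (bright parenchyma, dark fluid) or "t2like"
#'   (dark parenchyma, bright fluid).
#' @param lesion add two small contrast-inverted blobs.
#' @param seed integer seed; the phantom is a pure function of its arguments.
#' @return A \code{Phantom}.
#' @export
makePhantom <- function(shape = c(48L, 48L, 48L),
                        style = c("t1like", "t2like"),
                        lesion = FALSE, seed = 1L) {
  style <- match.arg(style)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 16L))
    stop("makePhantom: each extent must be >= 16")
  .withSeed(seed, {
    grids <- .coordGrids(shape)
    center <- (shape + 1) / 2 + stats::runif(3, -0.05, 0.05) * shape
    ## outer support: margin >= 2 voxels plus one voxel of slack, with a
    ## small random eccentricity
    semiOuter <- (shape / 2 - 3) * stats::runif(3, 0.92, 1.0)
    semiMid <- semiOuter * stats::runif(3, 0.72, 0.80)
    semiCore <- semiOuter * stats::runif(3, 0.28, 0.36)
    outer <- .ellipsoidMask(grids, center, semiOuter)
    mid <- .ellipsoidMask(grids, center, semiMid)
    core <- .ellipsoidMask(grids, center + 0.04 * shape * stats::runif(3, -1, 1),
                           semiCore)
    core <- core & mid
    lv <- switch(style,
      t1like = c(shell = 0.50, mid = 0.90, core = 0.20, lesion = 0.55),
      t2like = c(shell = 0.50, mid = 0.35, core = 1.00, lesion = 0.75))
    x <- array(0, shape)
    x[outer] <- lv["shell"]
    x[mid] <- lv["mid"]
    x[core] <- lv["core"]
    if (lesion) {
      for (i in 1:2) {
        ## place the blob well inside the middle shell
        dir <- stats::rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        rad <- max(2, round(min(shape) / 14))
        pos <- center + dir * semiMid * stats::runif(1, 0.35, 0.55)
        blob <- .ellipsoidMask(grids, pos, rep(rad, 3)) & mid & !core
        x[blob] <- lv["lesion"]
      }
    }
    new("Phantom", truth = IntensityVolume(x),
        support = RegionMask(array(as.numeric(outer), shape)),
        seed = as.integer(seed))
  })
}

## through-slice kernel weights at integer taps r = 0..(beta-1) offsets for
## rectangular; wider symmetric support around the block center for gaussian.
## Returned as list(offsets, weights) with sum(weights) == 1; offsets are
## relative to the first voxel of a block.
.sliceKernel <- function(profile, beta) {
  if (beta == 1L) return(list(offsets = 0L, weights = 1))
  if (profile@kind == "rectangular") {
    list(offsets = 0:(beta - 1L), weights = rep(1 / beta, beta))
  } else {
    fwhm <- profile@width * beta
    sigma <- fwhm / (2 * sqrt(2 * log(2)))
    centre <- (beta - 1) / 2
    span <- ceiling(3 * sigma)
    offs <- (-span):(beta - 1L + span)
    w <- exp(-((offs - centre)^2) / (2 * sigma^2))
    list(offsets = offs, weights = w / sum(w))
  }
}

## blur + block-aligned decimation along `axis` (circular boundary)
.blurDecimate <- function(a, axis, beta, kernel) {
  if (beta == 1L && length(kernel$offsets) == 1L) return(a)
  n <- dim(a)[axis]
  acc <- NULL
  for (i in seq_along(kernel$offsets)) {
    s <- .shift3(a, axis, kernel$offsets[i]) * kernel$weights[i]
    acc <- if (is.null(acc)) s else acc + s
  }
  ## keep every beta-th sample starting at the first voxel of each block
  keep <- seq(1L, n, by = beta)
  switch(axis,
         acc[keep, , , drop = FALSE],
         acc[, keep, , drop = FALSE],
         acc[, , keep, drop = FALSE])
}

## adjoint of .blurDecimate (used by image-domain fidelity baselines)
.blurDecimateAdj <- function(y, axis, beta, kernel, fullShape) {
  up <- array(0, fullShape)
  keep <- seq(1L, fullShape[axis], by = beta)
  if (axis == 1L) up[keep, , ] <- y
  else if (axis == 2L) up[, keep, ] <- y
  else up[, , keep] <- y
  acc <- array(0, fullShape)
  for (i in seq_along(kernel$offsets)) {
    acc <- acc + .shift3(up, axis, -kernel$offsets[i]) * kernel$weights[i]
  }
  acc
}

#' Simulate one anisotropic observation of a phantom
#'
#' Applies the acquisition model along the through-slice axis: circular
#' convolution with the slice profile (rectangular profile = non-overlapping
#' block means), decimation by \code{beta}, then i.i.d. additive Gaussian
#' noise with standard deviation \code{noisePct/100 * max(truth)}.
#'
#' @param p \code{Phantom}.
#' @param axis through-slice axis (1, 2 or 3).
#' @param beta integer downsampling factor; must divide the extent.
#' @param noisePct noise standard deviation as a percentage of the truth max.
#' @param profile \code{SliceProfile}.
#' @param seed seed for the noise draw.
#' @return An \code{Observation}.
#' @export
degrade <- function(p, axis, beta, noisePct = 0,
                    profile = SliceProfile("rectangular"), seed = 1L) {
  axis <- as.integer(axis)
  beta <- as.integer(beta)
  a <- .rawArray(truth(p))
  n <- dim(a)[axis]
  if (n %% beta != 0L) stop("degrade: extent along axis must be divisible by beta")
  kernel <- .sliceKernel(profile, beta)
  low <- .blurDecimate(a, axis, beta, kernel)
  if (noisePct > 0) {
    sigma <- noisePct / 100 * max(a)
    low <- low + .withSeed(seed, array(stats::rnorm(length(low), sd = sigma), dim(low)))
  }
  new("Observation", lowres = IntensityVolume(low), axis = axis, beta = beta,
      noisePct = noisePct, profile = profile)
}
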