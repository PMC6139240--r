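## Shared fixtures and independent oracles. Oracles are deliberately written
## as literal, slow formulas so they stay independent of the package's
## vectorized implementations.

randomVolume <- function(shape, seed) {
  set.seed(seed)
  IntensityVolume(array(stats::rnorm(prod(shape)), shape))
}

## literal O(N^2) triple-sum unitary DFT
naiveDFT3 <- function(a) {
  d <- dim(a)
  out <- array(0 + 0i, d)
  for (k1 in 0:(d[1] - 1)) for (k2 in 0:(d[2] - 1)) for (k3 in 0:(d[3] - 1)) {
    s <- 0 + 0i
    for (n1 in 0:(d[1] - 1)) for (n2 in 0:(d[2] - 1)) for (n3 in 0:(d[3] - 1)) {
      s <- s + a[n1 + 1, n2 + 1, n3 + 1] *
        exp(-2i * pi * (k1 * n1 / d[1] + k2 * n2 / d[2] + k3 * n3 / d[3]))
    }
    out[k1 + 1, k2 + 1, k3 + 1] <- s
  }
  out / sqrt(prod(d))
}

## literal isotropic TV: voxel loop over the defining formula, periodic wrap
naiveTV <- function(a) {
  d <- dim(a)
  tv <- 0
  for (s in 1:d[1]) for (t in 1:d[2]) for (u in 1:d[3]) {
    g1 <- a[s %% d[1] + 1, t, u] - a[s, t, u]
    g2 <- a[s, t %% d[2] + 1, u] - a[s, t, u]
    g3 <- a[s, t, u %% d[3] + 1] - a[s, t, u]
    tv <- tv + sqrt(g1^2 + g2^2 + g3^2)
  }
  tv
}

## small compactly supported two-shell ball phantom (margin > 2 everywhere)
ballPhantom <- function(n = 16, rOuter = 4, rInner = 2,
                        vOuter = 0.8, vInner = 0.3) {
  sh <- c(n, n, n)
  ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  d2 <- array(rowSums((co - ctr)^2), sh)
  x <- array(0, sh)
  x[d2 <= rOuter^2] <- vOuter
  x[d2 <= rInner^2] <- vInner
  new("Phantom", truth = IntensityVolume(x),
      support = RegionMask(array(as.numeric(d2 <= rOuter^2), sh)),
      seed = 0L)
}

## consistent noise-free spectrum instance: the observed coefficients are
## exactly the truth's spectrum restricted to the measured band of the
## standard two-view acquisition (so truth satisfies both constraint sets)
consistentInstance <- function(p, beta) {
  sh <- dim(truth(p))
  sim <- simulateAcquisition(p, beta = beta, noisePct = 0, seed = 1L)
  om <- omegaMask(sim$spectrum)
  X <- dft3(truth(p))@.Data
  new("AssembledSpectrum",
      f0prime = SpectrumVolume(X * om@.Data, symmetric = TRUE),
      omega = om, profileSpectrum = array(1, sh))
}

## degrade an arbitrary (possibly unsupported) volume with the package's
## acquisition operator, bypassing Phantom validity
degradeVolume <- function(a, axis, beta, profile = SliceProfile("rectangular")) {
  low <- SpecSR:::.blurDecimate(as.array(a), as.integer(axis), as.integer(beta),
                                SpecSR:::.sliceKernel(profile, as.integer(beta)))
  new("Observation", lowres = IntensityVolume(low), axis = as.integer(axis),
      beta = as.integer(beta), noisePct = 0, profile = profile)
}

## small solver state several ADMM steps in, for stationarity checks
warmedState <- function(asm, gam, cfg, steps = 4L) {
  st <- SpecSR:::.initState(asm, cfg)
  if (cfg@epsilon > 0) for (i in 1:3) st$m[[i]] <- st$x
  for (it in seq_len(steps)) {
    st$f <- updateF(st, asm, cfg)
    st$x <- updateX(st, gam, cfg)
    st$y <- updateY(st, cfg)
    if (cfg@epsilon > 0) st$m <- updateM(st, cfg)
    st <- updateDuals(st, asm, gam, cfg)
  }
  st
}

## tiny spectrum instance on a 6^3 grid with a cross-shaped band
tinyInstance <- function(seed = 7) {
  set.seed(seed)
  n <- 6L
  sh <- c(n, n, n)
  g <- SpecSR:::.coordGrids(sh)
  ball <- (g[[1]] - 3.5)^2 + (g[[2]] - 3.5)^2 + (g[[3]] - 3.5)^2 <= 2.2^2
  gam <- RegionMask(array(as.numeric(ball), sh))
  x0 <- array(0, sh)
  x0[ball] <- stats::runif(sum(ball))
  sk <- SpecSR:::.signedFreq(n)
  om <- array(0, sh)
  for (i in 1:n) for (k in 1:n)
    if (abs(sk[i]) < 2 || abs(sk[k]) < 2) om[i, , k] <- 1
  omM <- FrequencyMask(om)
  f0 <- SpectrumVolume(dft3(x0)@.Data * om, symmetric = TRUE)
  list(gamma = gam,
       asm = new("AssembledSpectrum", f0prime = f0, omega = omM,
                 profileSpectrum = array(1, sh)),
       truth = x0)
}

relErr <- function(a, b) {
  a <- as.array(a); b <- as.array(b)
  sqrt(sum((a - b)^2)) / max(sqrt(sum(b^2)), .Machine$double.eps)
}
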