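test_that("dft3 is unitary: Parseval, inner products and round trips", {
  v <- randomVolume(c(5, 4, 3), seed = 11)
  s <- dft3(v)
  expect_true(isSymmetric3(s))
  expect_equal(sqrt(sum(Mod(s@.Data)^2)), sqrt(sum(v@.Data^2)), tolerance = 1e-12)
  expect_lt(max(abs(idft3(s)@.Data - v@.Data)), 1e-12)

  u <- randomVolume(c(5, 4, 3), seed = 12)
  ip1 <- sum(Conj(dft3(u)@.Data) * dft3(v)@.Data)
  ip2 <- sum(u@.Data * v@.Data)
  expect_lt(Mod(ip1 - ip2), 1e-10)

  const <- IntensityVolume(array(2.5, c(4, 4, 4)))
  sc <- dft3(const)@.Data
  expect_equal(Re(sc[1, 1, 1]), 2.5 * sqrt(64), tolerance = 1e-12)
  expect_lt(max(Mod(sc[-1])), 1e-12)

  expect_error(dft3(array(c(NA, rep(0, 7)), c(2, 2, 2))), "finite")
})

test_that("dft3 matches an independently coded triple-loop DFT", {
  v <- randomVolume(c(4, 4, 4), seed = 0)
  expect_lt(max(Mod(dft3(v)@.Data - naiveDFT3(v@.Data))), 1e-8)
})

test_that("idft3 of a single conjugate pair is a sampled cosine", {
  n <- 8
  s <- array(0 + 0i, c(n, 1, 1))
  k <- 2
  amp <- 1.7
  s[k + 1, 1, 1] <- amp
  s[n - k + 1, 1, 1] <- amp
  x <- idft3(SpectrumVolume(s, symmetric = TRUE))@.Data
  expected <- 2 * amp / sqrt(n) * cos(2 * pi * k * (0:(n - 1)) / n)
  expect_lt(max(abs(as.vector(x) - expected)), 1e-8)
  expect_lt(max(abs(idft3(SpectrumVolume(array(0 + 0i, c(4, 4, 4))))@.Data)), 1e-15)
})

test_that("forward differences are periodic, linear, with the correct adjoint", {
  expect_lt(max(abs(forwardDiff(array(3, c(4, 4, 4)), 1)@.Data)), 1e-15)
  v <- array(c(0, 5), c(2, 1, 1))
  expect_equal(as.vector(forwardDiff(v, 1)@.Data), c(5, -5))
  expect_error(forwardDiff(array(0, c(2, 2, 2)), 4), "axis")

  v <- randomVolume(c(5, 4, 3), 21)@.Data
  w <- randomVolume(c(5, 4, 3), 22)@.Data
  for (ax in 1:3) {
    lhs <- sum(forwardDiff(v, ax)@.Data * w)
    rhs <- sum(v * SpecSR:::.diffAdj(w, ax))
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("total variation matches its defining triple-loop formula", {
  expect_equal(totalVariation(array(7, c(3, 3, 3))), 0)
  v <- randomVolume(c(4, 4, 4), seed = 1)
  expect_equal(totalVariation(v), naiveTV(v@.Data), tolerance = 1e-12)
  expect_equal(totalVariation(IntensityVolume(-2.3 * v@.Data)),
               2.3 * totalVariation(v), tolerance = 1e-10)
  expect_equal(totalVariation(IntensityVolume(v@.Data + 4.2)),
               totalVariation(v), tolerance = 1e-10)
})

test_that("unfold/fold are exact inverses with the right shapes", {
  t <- randomVolume(c(2, 3, 4), 31)@.Data
  expect_identical(dim(unfoldTensor(t, 1)), c(2L, 12L))
  expect_identical(dim(unfoldTensor(t, 2)), c(3L, 8L))
  for (i in 1:3) {
    m <- unfoldTensor(t, i)
    expect_equal(sum(m^2), sum(t^2))            # permutation of entries
    expect_identical(foldTensor(m, i, c(2, 3, 4)), t)
  }
  expect_error(foldTensor(unfoldTensor(t, 1), 2, c(2, 3, 4)), "inconsistent")
})

test_that("svt shrinks singular values and is a proximal operator", {
  m <- diag(c(5, 2))
  expect_equal(svt(m, 2), diag(c(3, 0)), tolerance = 1e-12)
  A <- matrix(stats::rnorm(20), 5, 4)
  expect_equal(svt(A, 0), A, tolerance = 1e-12)

  set.seed(2)
  A <- matrix(stats::rnorm(20), 5, 4)
  tau <- stats::median(svd(A)$d)
  B <- svt(A, tau)
  expect_equal(svd(B)$d, pmax(svd(A)$d - tau, 0), tolerance = 1e-10)
  expect_equal(svt(A, tau, method = "gram"), B, tolerance = 1e-9)

  obj <- function(B) 0.5 * sum((A - B)^2) + tau * sum(svd(B)$d)
  base <- obj(B)
  set.seed(3)
  for (i in 1:200) {
    P <- B + matrix(stats::rnorm(20, sd = 0.01), 5, 4)
    expect_gte(obj(P), base - 1e-10)
  }
  expect_error(svt(matrix(1i, 1, 1), 1), "complex")
})

test_that("svt is nonexpansive", {
  set.seed(4)
  for (i in 1:20) {
    A <- matrix(stats::rnorm(12), 4, 3)
    B <- matrix(stats::rnorm(12), 4, 3)
    tau <- stats::runif(1, 0, 2)
    expect_lte(sqrt(sum((svt(A, tau) - svt(B, tau))^2)),
               sqrt(sum((A - B)^2)) + 1e-12)
  }
})

test_that("tensor trace norm: rank-1 closed form and Frobenius lower bound", {
  expect_equal(tensorTraceNorm(array(0, c(3, 3, 3))), 0)
  set.seed(5)
  a <- stats::rnorm(4); b <- stats::rnorm(5); c <- stats::rnorm(3)
  t1 <- outer(outer(a, b), c)
  expected <- sqrt(sum(a^2)) * sqrt(sum(b^2)) * sqrt(sum(c^2))
  expect_equal(tensorTraceNorm(t1), expected, tolerance = 1e-10)
  w <- ModeWeights(c(0.5, 0.3, 0.2))
  expect_equal(tensorTraceNorm(t1, w), expected, tolerance = 1e-10)

  for (i in 1:10) {
    t <- randomVolume(c(4, 3, 5), 100 + i)@.Data
    fro <- sqrt(sum(t^2))
    expect_gte(tensorTraceNorm(t), fro - 1e-10)
  }
})

test_that("group soft-thresholding shrinks per-voxel gradient vectors", {
  g <- lapply(1:3, function(i) randomVolume(c(3, 3, 3), 40 + i)@.Data)
  expect_identical(groupSoftThreshold(g, 0), g)

  v <- list(array(3, c(1, 1, 1)), array(0, c(1, 1, 1)), array(0, c(1, 1, 1)))
  out <- groupSoftThreshold(v, 1)
  expect_equal(as.numeric(out[[1]]), 2)
  expect_equal(as.numeric(out[[2]]), 0)

  small <- lapply(1:3, function(i) array(0.1, c(2, 2, 2)))
  out <- groupSoftThreshold(small, 10)
  expect_true(all(vapply(out, function(a) all(a == 0), logical(1))))
})

test_that("spectrum volumes validate conjugate symmetry", {
  v <- randomVolume(c(4, 4, 4), 50)
  expect_silent(SpectrumVolume(dft3(v)@.Data, symmetric = TRUE))
  bad <- dft3(v)@.Data
  bad[2, 1, 1] <- bad[2, 1, 1] + 1
  expect_error(SpectrumVolume(bad, symmetric = TRUE), "symmetry")
})
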