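test_that("edge mask flags the configured fraction of strongest gradients", {
  g <- voxelGrid(c(24, 24, 24), 1)
  co <- coords(g)
  roi <- co$x^2 + co$y^2 + co$z^2 <= 10^2
  # constant magnitude: no edges anywhere
  m0 <- edgeMask(array(1, g@shape), roi)
  expect_true(all(vapply(m0, function(m) all(m == 1), TRUE)))
  # continuous random magnitude: 30% of ROI flagged per direction, and the
  # masks agree with a brute-force sort-and-threshold
  set.seed(3)
  mag <- array(rnorm(prod(g@shape)), g@shape)
  em <- edgeMask(mag, roi, maskFraction = 0.30)
  nroi <- sum(roi)
  for (ax in 1:3) {
    frac <- sum(em[[ax]] == 0 & roi) / nroi
    expect_equal(frac, 0.30, tolerance = 2 / nroi + 1e-9)
    gabs <- abs(msdiqsm:::gradAxis(mag, ax, 1))
    thr <- sort(gabs[roi])[ceiling(0.7 * nroi)]
    ref <- array(1, g@shape); ref[roi & gabs > thr] <- 0
    expect_lt(mean(ref != em[[ax]]), 2 / nroi)
  }
})

test_that("reliability mask zeroes the scale-dependent top percentiles", {
  dims <- c(20, 20, 20)
  roi <- array(TRUE, dims)
  set.seed(4)
  sd2 <- array(runif(prod(dims)), dims)
  # scale 1 is fully trusted
  expect_true(all(reliabilityMask(sd2, roi, 1) == 1))
  # defaults q = 10, radii 2/4/8/16: masked fractions 10/20/40% at scales 2-4
  for (case in list(c(2, 0.10), c(3, 0.20), c(4, 0.40))) {
    m <- reliabilityMask(sd2, roi, case[1])
    expect_equal(mean(m == 0), case[2], tolerance = 1e-3)
  }
  # 10 distinct toy values, effective percent 20: exactly the 2 largest go
  toy <- array(0, c(17, 17, 17)); toy[1:10] <- 1:10
  toyRoi <- array(FALSE, c(17, 17, 17)); toyRoi[1:10] <- TRUE
  m <- reliabilityMask(toy, toyRoi, 2, qPercent = 20, radiiMm = c(2, 4))
  expect_equal(which(m[toyRoi] == 0), c(9, 10))
  # an over-100% effective percentile is rejected
  expect_error(reliabilityMask(sd2, roi, 4, qPercent = 30,
                               radiiMm = c(2, 4, 8, 16)), "percentile")
})

test_that("MERIT reweighting downweights only large residuals, squared", {
  dims <- c(6, 6, 6)
  a <- array(1, dims)
  r <- array(1, dims)
  expect_equal(meritReweight(a, r, f = 6), a) # below threshold: unchanged
  r[1, 1, 1] <- 10
  w <- meritReweight(a, r, f = 6)
  expect_equal(w[1, 1, 1], 0.01) # a'/r^2 = 1/100
  expect_equal(w[2:6, , ], a[2:6, , ])
  # never increases a weight
  set.seed(6)
  a2 <- array(runif(prod(dims)), dims)
  r2 <- array(rexp(prod(dims), rate = 0.3), dims)
  expect_true(all(meritReweight(a2, r2) <= a2 + 1e-15))
})

test_that("solveScale returns zero for zero phase and matches a dense oracle", {
  f <- smallKernels(n = 16L, radii = 2)
  g <- f$grid; ks <- f$kernels
  ones <- array(1, g@shape)
  sp <- scaleSpec(rMm = 2, lambda = 10^2.7)
  z <- solveScale(array(0, g@shape), ones, ones, NULL, ks, 1, sp)
  expect_equal(max(abs(z@chiDelta)), 0)
  expect_true(z@converged)

  # dense linearised least-squares oracle: one Gauss-Newton step from X = 0,
  # normal equations assembled as explicit matrices and solved directly.
  # Tight CG isolates the operator assembly from CG truncation error.
  co <- coords(g)
  chi <- array(0, g@shape); chi[co$x^2 + co$y^2 + co$z^2 <= 3^2] <- 0.1
  phi <- ks@chiToPhase * forwardField(chi, ks, highpassScale = 1)
  spT <- scaleSpec(rMm = 2, lambda = 10^2.7, maxOuter = 1L, cgTol = 1e-8,
                   maxCg = 3000L)
  res <- solveScale(phi, ones, ones, NULL, ks, 1, spT)
  N <- prod(g@shape)
  op <- (1 - ks@smvHat[[1]]) * ks@dipole * ks@chiToPhase
  Cfun <- function(x) Re(fft(op * fft(array(x, g@shape)), inverse = TRUE)) / N
  regH <- function(x) as.vector(msdiqsm:::div3Adjoint(
    msdiqsm:::grad3(array(x, g@shape), g@voxelSize), g@voxelSize))
  Cm <- matrix(0, N, N); Rm <- matrix(0, N, N); e <- numeric(N)
  for (j in 1:N) {
    e[j] <- 1; Cm[, j] <- as.vector(Cfun(e)); Rm[, j] <- regH(e); e[j] <- 0
  }
  H <- Rm / sqrt(spT@epsilon) + 2 * spT@lambda * crossprod(Cm)
  H <- H + mean(diag(H)) / N # pin the constant null space (zero-mean soln)
  rhs <- -(2 * spT@lambda * t(Cm) %*% as.vector(sin(-phi)))
  oracle <- array(as.vector(solve(H, rhs)), g@shape)
  relRmse <- sqrt(sum((res@chiDelta - oracle)^2)) / sqrt(sum(oracle^2))
  expect_lt(relRmse, 0.10)
})

test_that("gradient and divergence are exact adjoints", {
  g <- voxelGrid(c(9, 10, 11), c(1, 1.2, 0.8))
  set.seed(8)
  x <- array(rnorm(prod(g@shape)), g@shape)
  y <- lapply(1:3, function(i) array(rnorm(prod(g@shape)), g@shape))
  gx <- msdiqsm:::grad3(x, g@voxelSize)
  lhs <- sum(gx[[1]] * y[[1]] + gx[[2]] * y[[2]] + gx[[3]] * y[[3]])
  rhs <- sum(x * msdiqsm:::div3Adjoint(y, g@voxelSize))
  expect_equal(lhs, rhs, tolerance = 1e-12)
  # gradient of a constant vanishes (DC-blind regulariser)
  gc <- msdiqsm:::grad3(array(5, g@shape), g@voxelSize)
  expect_true(all(vapply(gc, function(a) max(abs(a)) == 0, TRUE)))
})

test_that("masks are binary and idempotent under application", {
  dims <- c(12, 12, 12)
  set.seed(10)
  sd2 <- array(runif(prod(dims)), dims)
  roi <- array(TRUE, dims)
  q <- reliabilityMask(sd2, roi, 3)
  expect_true(all(q %in% c(0, 1)))
  x <- array(rnorm(prod(dims)), dims)
  expect_equal((x * q) * q, x * q)
})

test_that("stronger regularisation never increases total variation", {
  f <- stdAcquisition(n = 32L)
  tv <- function(x) {
    gr <- msdiqsm:::grad3(x, f$phantom$grid@voxelSize)
    sum(abs(gr[[1]])) + sum(abs(gr[[2]])) + sum(abs(gr[[3]]))
  }
  lams <- 10^seq(1.4, 3.0, by = 0.4) # 5-point grid
  tvs <- vapply(lams, function(l) {
    r <- runMSDI(f$phi, f$acq$noisyMagnitude, f$phantom$roi,
                 msdiConfig(radiiMm = 2, lambda = l))
    tv(susceptibilityMap(r))
  }, numeric(1))
  # smaller lambda = stronger smoothing = lower (or equal) total variation
  expect_true(all(diff(tvs) >= -1e-6 * tvs[-1]))
})
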