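test_that("Laplacian unwrap is the identity (up to DC) on smooth phase", {
  g <- voxelGrid(c(48, 48, 48), 1)
  co <- coords(g)
  phi0 <- 0.05 * sin(2 * pi * co$x / 48) * cos(2 * pi * co$y / 48)
  u <- laplacianUnwrap(fieldVolume(phi0, g, 20, 3))
  expect_equal(fieldUnits(u), "rad")
  expect_lt(max(abs(fieldValues(u) - (phi0 - mean(phi0)))), 1e-6)
  expect_equal(mean(fieldValues(u)), 0, tolerance = 1e-12)
})

test_that("Laplacian unwrap recovers a wrapped 4*pi linear ramp", {
  g <- voxelGrid(c(48, 48, 48), 1)
  co <- coords(g)
  ramp <- 4 * pi * (co$x + 24) / 48
  wrapped <- (ramp + pi) %% (2 * pi) - pi
  u <- laplacianUnwrap(fieldVolume(wrapped, g, 20, 3))
  inner <- abs(co$x) < 20 & abs(co$y) < 20 & abs(co$z) < 20
  expect_gt(cor(fieldValues(u)[inner], ramp[inner]), 0.999)
})

test_that("Laplacian unwrap recovers a wrapping phantom field", {
  # wraps driven by a strong smooth background source so the peak in-ROI
  # |phase| is ~2 pi while the data stay Nyquist-sampled (the in vivo
  # situation: wraps come from background fields, not local sources)
  spec <- standardPhantom(snr = Inf)
  spec@backgroundSources <- list(list(position = c(0, 0, 60), moment = 6000))
  ph <- makePhantom(spec)
  acq <- simulateAcquisition(ph, spec)
  truthPhase <- chiToPhaseFactor(spec@teMs, spec@b0T) * acq$fieldPpm
  expect_gt(max(abs(truthPhase[ph$roi])), 5) # peak ~2 pi: it does wrap
  u <- laplacianUnwrap(acq$wrappedPhase)
  co <- coords(ph$grid)
  interior <- co$x^2 + co$y^2 + co$z^2 <= 25^2
  err <- fieldValues(u) - truthPhase
  err <- err - mean(err[interior])
  expect_lt(sqrt(sum(err[interior]^2) / sum(truthPhase[interior]^2)), 0.02)
})

test_that("vSMV removes constants and suppresses external sources", {
  g <- voxelGrid(c(48, 48, 48), 1)
  co <- coords(g)
  roi <- co$x^2 + co$y^2 + co$z^2 <= 20^2
  cst <- fieldVolume(array(2.5, g@shape), g, 20, 3)
  v <- vsmvBackgroundRemoval(cst, roi, r0Mm = 40)
  expect_lt(max(abs(fieldValues(v$field))), 1e-10)
  # output ROI loses only the rmin (1 voxel) shell
  expect_true(all(v$roi[roi & co$x^2 + co$y^2 + co$z^2 <= 18.9^2]))
  expect_true(!any(v$roi & !roi))
  # harmonic field from an outside source: >= 95% suppression inside
  bg <- analyticPointSourceField(1, c(0, 0, 22.5), g)
  vb <- vsmvBackgroundRemoval(fieldVolume(bg, g, 20, 3), roi, r0Mm = 40)
  supp <- sqrt(sum(fieldValues(vb$field)[vb$roi]^2) / sum(bg[vb$roi]^2))
  expect_lt(supp, 0.05)
  # degenerate ROI: kernel fits nowhere
  tiny <- array(FALSE, g@shape); tiny[24, 24, 24] <- TRUE
  expect_error(vsmvBackgroundRemoval(cst, tiny, r0Mm = 5), "nowhere")
})

test_that("field normalisation is the TE.B0 = 60 ms.T scaling, unit-tracked", {
  g <- voxelGrid(c(8, 8, 8), 1)
  vals <- array(1, g@shape)
  n1 <- normalizeField(fieldVolume(vals, g, teMs = 20, b0T = 3))
  expect_equal(fieldValues(n1)[1], 1) # TE.B0 = 60 -> factor 1
  n2 <- normalizeField(fieldVolume(vals, g, teMs = 40, b0T = 3))
  expect_equal(fieldValues(n2)[1], 0.5) # TE.B0 = 120 -> factor 0.5
  n3 <- normalizeField(fieldVolume(vals, g, teMs = 10, b0T = 3))
  expect_equal(fieldValues(n3)[1], 2) # TE.B0 = 30 -> factor 2
  expect_equal(fieldUnits(n1), "normalised")
  expect_error(normalizeField(n1), "twice")
  expect_error(normalizeField(fieldVolume(vals, g)), "teMs")
})

test_that("noise weights follow the composite inverse-noise formula", {
  f <- smallKernels(n = 24L, radii = 4)
  g <- f$grid
  co <- coords(g)
  roi <- co$x^2 + co$y^2 + co$z^2 <= 9^2
  hat <- f$kernels@smvHat[[1]]
  # uniform magnitude: Ahat = Ahat_l = 1 -> weight = 2^(-1/2) in the ROI
  w <- noiseWeight(array(3, g@shape), roi, hat)
  expect_equal(unname(w[roi][1]), 2^-0.5, tolerance = 1e-9)
  expect_true(all(w[!roi] == 0))
  # brute-force evaluation of the formula on a random magnitude
  set.seed(5)
  mag <- array(exp(rnorm(prod(g@shape), sd = 0.2)), g@shape)
  w2 <- noiseWeight(mag, roi, hat)
  ahat <- array(0, g@shape); ahat[roi] <- mag[roi] / mean(mag[roi])
  sm <- smvFilter(mag, hat, roi = roi)
  ahatl <- array(0, g@shape); ahatl[roi] <- sm[roi] / mean(sm[roi])
  ref <- array(0, g@shape)
  ref[roi] <- (ahat[roi]^-2 + ahatl[roi]^-2)^-0.5
  expect_equal(w2, ref, tolerance = 1e-12)
  # ROI means of the normalised terms are 1 by construction
  expect_equal(mean(ahat[roi]), 1, tolerance = 1e-9)
  expect_equal(mean(ahatl[roi]), 1, tolerance = 1e-9)
  # monotone in local magnitude: halved magnitude lowers the weight
  mag3 <- array(1, g@shape); mag3[co$x > 0] <- 0.5
  w3 <- noiseWeight(mag3, roi, hat)
  expect_lt(mean(w3[roi & co$x > 2]), mean(w3[roi & co$x < -2]))
  # dead voxels clamp to zero with a warning
  mag4 <- array(1, g@shape); mag4[12, 12, 12] <- 0
  expect_warning(w4 <- noiseWeight(mag4, roi, hat), "clamped")
  expect_equal(w4[12, 12, 12], 0)
})

test_that("second-difference map matches a brute-force 13-direction loop", {
  g <- voxelGrid(c(9, 8, 7), 1)
  co <- coords(g)
  # linear ramp: zero second differences in the interior
  sd1 <- secondDifferenceMap(2 * co$x + 3 * co$y - co$z)
  expect_lt(max(abs(sd1[2:8, 2:7, 2:6])), 1e-10)
  # phi = x^2: each of the 9 directions with an x-component has second
  # difference exactly 2, the other 4 zero -> RSS = sqrt(9 * 4) = 6
  sdx <- secondDifferenceMap(co$x^2)
  expect_equal(unname(sdx[3:7, 3:6, 3:5][1]), 6, tolerance = 1e-12)
  expect_lt(diff(range(sdx[3:7, 3:6, 3:5])), 1e-10)
  # wrapped mode: a steep ramp wrapped into [-pi, pi) still has zero second
  # differences when first differences are rewrapped
  ramp <- (2.5 * co$x + pi) %% (2 * pi) - pi
  sdw <- secondDifferenceMap(ramp, wrapped = TRUE)
  expect_lt(max(abs(sdw[2:8, 2:7, 2:6])), 1e-10)
  # brute force over all 13 unique directions on a random volume
  set.seed(9)
  phi <- array(rnorm(prod(g@shape)), g@shape)
  got <- secondDifferenceMap(phi)
  dirs <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  dirs <- dirs[!(dirs$x == 0 & dirs$y == 0 & dirs$z == 0), ]
  dirs <- dirs[apply(dirs, 1, function(d) d[d != 0][1] > 0), ]
  ref <- array(0, g@shape)
  d <- dim(phi)
  for (i in seq_len(nrow(dirs))) {
    dd <- as.numeric(dirs[i, ])
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      p <- c(x, y, z) + dd; q <- c(x, y, z) - dd
      if (all(p >= 1) && all(p <= d) && all(q >= 1) && all(q <= d)) {
        s2 <- phi[p[1], p[2], p[3]] - 2 * phi[x, y, z] + phi[q[1], q[2], q[3]]
        ref[x, y, z] <- ref[x, y, z] + s2^2
      }
    }
  }
  expect_equal(got, sqrt(ref), tolerance = 1e-12)
})
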