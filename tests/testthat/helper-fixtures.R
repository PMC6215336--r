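# Shared fixtures. Expensive phantom acquisitions are memoised per test run
# so several test files can reuse the same simulated scan.

.fixtureCache <- new.env(parent = emptyenv())

# Standard phantom acquisition: rasterised scene, simulated scan, unwrapped
# and normalised field. Keyed by background scale and grid size.
stdAcquisition <- function(backgroundScale = 1, n = 64L) {
  key <- sprintf("acq_%g_%d", backgroundScale, n)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  spec <- standardPhantom(backgroundScale = backgroundScale, n = n)
  ph <- makePhantom(spec)
  acq <- simulateAcquisition(ph, spec)
  phi <- normalizeField(laplacianUnwrap(acq$wrappedPhase))
  out <- list(spec = spec, phantom = ph, acq = acq, phi = phi)
  .fixtureCache[[key]] <- out
  out
}

# Full four-scale inversion of the standard phantom (raw chain), memoised.
stdInversion <- function(n = 64L) {
  key <- sprintf("msdi_%d", n)
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  f <- stdAcquisition(n = n)
  res <- runMSDI(f$phi, f$acq$noisyMagnitude, f$phantom$roi, msdiConfig())
  .fixtureCache[[key]] <- res
  res
}

# Small grid + kernels for operator-level tests.
smallKernels <- function(n = 16L, radii = c(2, 4)) {
  key <- sprintf("ker_%d_%s", n, paste(radii, collapse = "_"))
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  g <- voxelGrid(rep(n, 3L), 1)
  ks <- kernelSet(g, radiiMm = radii, teMs = 60, b0T = 1)
  out <- list(grid = g, kernels = ks)
  .fixtureCache[[key]] <- out
  out
}

# mm coordinates relative to the volume centre (mirrors the phantom module).
coords <- function(grid) {
  ax <- function(n, d) (seq_len(n) - (floor(n / 2) + 1)) * d
  nx <- grid@shape[1]; ny <- grid@shape[2]; nz <- grid@shape[3]
  x <- ax(nx, grid@voxelSize[1]); y <- ax(ny, grid@voxelSize[2])
  z <- ax(nz, grid@voxelSize[3])
  list(
    x = array(rep(x, times = ny * nz), grid@shape),
    y = array(rep(rep(y, each = nx), times = nz), grid@shape),
    z = array(rep(z, each = nx * ny), grid@shape)
  )
}
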