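# Synthetic susceptibility phantoms and acquisition simulation. These scenes
# provide the ground truth for every end-to-end test: piecewise-constant
# susceptibility objects inside a spherical ROI, harmonic background fields
# from point dipole sources outside it, and complex-Gaussian measurement
# noise.

#' Construct a phantom specification
#'
#' @param grid a [VoxelGrid-class].
#' @param objects list of object descriptors; each a list with `shape`
#'   (`"sphere"`, `"ellipsoid"`, `"box"`, `"cylinder"`), `centre` (mm offsets
#'   from the volume centre), `size` (radius in mm for spheres/cylinders,
#'   semi-axes for ellipsoids, edge lengths for boxes), `chiPpm`, and for
#'   cylinders `axis` (unit direction) and `length` (mm).
#' @param backgroundSources list of `list(position = mm offsets, moment =
#'   ppm mm^3)` point dipoles strictly outside the ROI.
#' @param roiRadiusMm spherical ROI radius (mm).
#' @param snr magnitude signal-to-noise ratio (Inf for noise-free).
#' @param teMs,b0T acquisition constants.
#' @param seed RNG seed for the noise draw.
#' @return A [PhantomSpec-class].
#' @export
phantomSpec <- function(grid, objects = list(), backgroundSources = list(),
                        roiRadiusMm, snr = Inf, teMs = 20, b0T = 3,
                        seed = 1234L) {
  new("PhantomSpec", grid = grid, objects = objects,
      backgroundSources = backgroundSources,
      roiRadiusMm = roiRadiusMm, snr = snr, teMs = teMs, b0T = b0T,
      seed = as.integer(seed))
}

#' The standard validation phantom
#'
#' A 64^3, 1 mm isotropic scene with a 28 mm spherical ROI containing three
#' "nuclei" spheres (0.05, 0.10, 0.20 ppm), two 1.5 mm radius paramagnetic
#' cylinders along B0 (0.45 ppm, venous-blood-like), one diamagnetic slab
#' (-0.05 ppm), and two external dipole sources just outside the ROI.
#' TE.B0 = 60 ms.T so field normalisation is the identity, SNR 50, seed 1234.
#'
#' @param snr override the default SNR of 50.
#' @param seed override the default seed of 1234.
#' @param backgroundScale multiplier on the external source moments (0 turns
#'   the background off).
#' @param n grid size per axis; the voxel size scales as 64/n so the scene
#'   geometry in mm is unchanged (n = 32 gives the same phantom at 2 mm).
#' @return A [PhantomSpec-class].
#' @export
standardPhantom <- function(snr = 50, seed = 1234L, backgroundScale = 1,
                            n = 64L) {
  grid <- voxelGrid(rep(as.integer(n), 3L), 64 / n)
  objects <- list(
    list(shape = "sphere", centre = c(-12, -8, 0), size = 6, chiPpm = 0.05),
    list(shape = "sphere", centre = c(12, -8, 0), size = 5, chiPpm = 0.10),
    list(shape = "sphere", centre = c(0, 12, 6), size = 4, chiPpm = 0.20),
    list(shape = "cylinder", centre = c(-6, 8, 0), size = 1.5, chiPpm = 0.45,
         axis = c(0, 0, 1), length = 40),
    list(shape = "cylinder", centre = c(8, 4, 0), size = 1.5, chiPpm = 0.45,
         axis = c(0, 0, 1), length = 40),
    list(shape = "box", centre = c(0, -16, -10), size = c(20, 10, 6),
         chiPpm = -0.05)
  )
  # Moments are capped by the phase-sampling (Nyquist) constraint: the
  # wrapped in-ROI phase gradient must stay below pi per voxel for the data
  # to be measurable at all. At ~2.5 mm from the ROI these moments give
  # boundary fields of ~0.1-0.15 ppm (~2 rad at TE.B0 = 60 ms.T) with peak
  # in-ROI gradients of ~pi/2 per voxel.
  sources <- list(
    list(position = c(0, 0, 30.5), moment = 1.0 * backgroundScale),
    list(position = c(-24, 0, -19), moment = -0.8 * backgroundScale)
  )
  phantomSpec(grid, objects, sources, roiRadiusMm = 28, snr = snr,
              teMs = 20, b0T = 3, seed = seed)
}

# mm coordinate arrays relative to the volume centre.
centredCoords <- function(grid) {
  ax <- function(n, d) (seq_len(n) - (floor(n / 2) + 1)) * d
  axisArrays(ax(grid@shape[1], grid@voxelSize[1]),
             ax(grid@shape[2], grid@voxelSize[2]),
             ax(grid@shape[3], grid@voxelSize[3]))
}

rasteriseObject <- function(obj, co) {
  cx <- co$x - obj$centre[1]
  cy <- co$y - obj$centre[2]
  cz <- co$z - obj$centre[3]
  switch(obj$shape,
    sphere = cx^2 + cy^2 + cz^2 <= obj$size[1]^2,
    ellipsoid = (cx / obj$size[1])^2 + (cy / obj$size[2])^2 +
      (cz / obj$size[3])^2 <= 1,
    box = abs(cx) <= obj$size[1] / 2 & abs(cy) <= obj$size[2] / 2 &
      abs(cz) <= obj$size[3] / 2,
    cylinder = {
      a <- obj$axis / sqrt(sum(obj$axis^2))
      t <- cx * a[1] + cy * a[2] + cz * a[3]
      p2 <- cx^2 + cy^2 + cz^2 - t^2
      p2 <= obj$size[1]^2 & abs(t) <= obj$length / 2
    },
    stop(sprintf("unknown object shape '%s'", obj$shape))
  )
}

#' Rasterise a phantom scene
#'
#' Builds the piecewise-constant susceptibility volume (later objects win
#' where they overlap), an integer label map (one label per object), the
#' spherical ROI, and a tissue-dependent magnitude with a smooth
#' receive-bias-like modulation. Deterministic: no RNG involved.
#'
#' @param spec a [PhantomSpec-class].
#' @return List with `chi` (ppm), `magnitude`, `roi` (logical), `labels`
#'   (integer), and `grid`.
#' @export
makePhantom <- function(spec) {
  grid <- spec@grid
  co <- centredCoords(grid)
  chi <- array(0, grid@shape)
  labels <- array(0L, grid@shape)
  for (i in seq_along(spec@objects)) {
    inside <- rasteriseObject(spec@objects[[i]], co)
    chi[inside] <- spec@objects[[i]]$chiPpm
    labels[inside] <- i
  }
  roi <- co$x^2 + co$y^2 + co$z^2 <= spec@roiRadiusMm^2
  # Tissue-dependent magnitude: veins dark, nuclei slightly hypointense,
  # smooth multiplicative bias; near-zero signal outside the head.
  fov <- grid@shape * grid@voxelSize
  bias <- 1 + 0.15 * sin(pi * (co$x / fov[1] + 0.3)) *
    cos(pi * co$y / fov[2]) + 0.05 * co$z / fov[3]
  magnitude <- array(0.05, grid@shape)
  magnitude[roi] <- 1
  for (i in seq_along(spec@objects)) {
    obj <- spec@objects[[i]]
    att <- if (obj$shape == "cylinder") 0.4 else 0.9
    magnitude[labels == i] <- magnitude[labels == i] * att
  }
  magnitude <- magnitude * bias
  list(chi = chi, magnitude = magnitude, roi = roi, labels = labels,
       grid = grid)
}

#' Analytic external field of a uniform sphere
#'
#' Closed-form dipole field (in ppm, same convention as [forwardField()]):
#' exterior `(chi/3) (a/r)^3 (3 cos^2 theta - 1)` with theta measured from
#' the B0 direction; zero inside the sphere (the Lorentz-corrected interior
#' field of a uniform sphere vanishes).
#'
#' @param chiPpm susceptibility contrast of the sphere (ppm).
#' @param radiusMm sphere radius (mm).
#' @param grid a [VoxelGrid-class].
#' @param centreMm centre offset from the volume centre (mm).
#' @return 3D field array (ppm).
#' @export
analyticSphereField <- function(chiPpm, radiusMm, grid,
                                centreMm = c(0, 0, 0)) {
  co <- centredCoords(grid)
  cx <- co$x - centreMm[1]; cy <- co$y - centreMm[2]; cz <- co$z - centreMm[3]
  r2 <- cx^2 + cy^2 + cz^2
  proj <- cx * grid@b0Dir[1] + cy * grid@b0Dir[2] + cz * grid@b0Dir[3]
  f <- array(0, grid@shape)
  out <- r2 > radiusMm^2
  f[out] <- (chiPpm / 3) * (radiusMm^3 / r2[out]^1.5) *
    (3 * proj[out]^2 / r2[out] - 1)
  f
}

#' Analytic field of a point dipole source
#'
#' `moment * (3 cos^2 theta - 1) / r^3` (ppm with r in mm): the far field of
#' a small susceptibility inclusion of strength `moment = chi a^3 / 3`.
#' Harmonic away from the source, so it is exactly the kind of background a
#' spherical-mean-value filter should annihilate.
#'
#' @param momentPpmMm3 dipole strength (ppm mm^3).
#' @param positionMm source position relative to the volume centre (mm).
#' @param grid a [VoxelGrid-class].
#' @return 3D field array (ppm); clamped to 0 within half a voxel of the
#'   source to avoid the singularity.
#' @export
analyticPointSourceField <- function(momentPpmMm3, positionMm, grid) {
  co <- centredCoords(grid)
  cx <- co$x - positionMm[1]
  cy <- co$y - positionMm[2]
  cz <- co$z - positionMm[3]
  r2 <- cx^2 + cy^2 + cz^2
  proj <- cx * grid@b0Dir[1] + cy * grid@b0Dir[2] + cz * grid@b0Dir[3]
  f <- array(0, grid@shape)
  ok <- r2 > (min(grid@voxelSize) / 2)^2
  f[ok] <- momentPpmMm3 * (3 * proj[ok]^2 / r2[ok] - 1) / r2[ok]^1.5
  f
}

#' Simulate a gradient-echo acquisition of a phantom
#'
#' Computes the total field (k-space forward model of the scene plus the
#' analytic fields of all background sources), converts to phase with the
#' chi-to-phase constant for the spec's TE and B0, forms the complex signal
#' `magnitude * exp(i phase)` and adds i.i.d. complex Gaussian noise with a
#' per-channel standard deviation of `mean(magnitude in ROI) / snr`. Seeded
#' and deterministic.
#'
#' @param phantom output of [makePhantom()].
#' @param spec the [PhantomSpec-class] used to build it.
#' @return List with `wrappedPhase` ([FieldVolume-class], rad, in [-pi, pi)),
#'   `noisyMagnitude`, `fieldPpm` (the noise-free total field) and
#'   `localFieldPpm` (sources inside the ROI only).
#' @export
simulateAcquisition <- function(phantom, spec) {
  grid <- spec@grid
  kernels <- kernelSet(grid, radiiMm = max(grid@voxelSize),
                       teMs = spec@teMs, b0T = spec@b0T)
  local <- forwardField(phantom$chi, kernels)
  bg <- array(0, grid@shape)
  for (s in spec@backgroundSources)
    bg <- bg + analyticPointSourceField(s$moment, s$position, grid)
  field <- local + bg
  phase <- kernels@chiToPhase * field
  signal <- phantom$magnitude * exp(1i * phase)
  if (is.finite(spec@snr)) {
    sigma <- mean(phantom$magnitude[phantom$roi]) / spec@snr
    noise <- withSeed(spec@seed, {
      n <- length(signal)
      complex(real = stats::rnorm(n, sd = sigma),
              imaginary = stats::rnorm(n, sd = sigma))
    })
    signal <- signal + array(noise, dim(signal))
  }
  list(
    wrappedPhase = fieldVolume(Arg(signal), grid, teMs = spec@teMs,
                               b0T = spec@b0T, units = "rad"),
    noisyMagnitude = Mod(signal),
    fieldPpm = field,
    localFieldPpm = local
  )
}
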