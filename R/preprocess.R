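# Pre-inversion chain: Laplacian phase unwrapping, variable-kernel SMV
# background-field removal, TE.B0 field normalisation, magnitude-derived
# noise weights, and the phase second-difference quality map.

# Transfer function of the periodic 7-point discrete Laplacian for an
# arbitrary shape (used on the mirror-extended domain).
laplacianHatDims <- function(n, h) {
  e <- function(nn, hh) 2 * (cos(2 * pi * (0:(nn - 1)) / nn) - 1) / hh^2
  a <- axisArrays(e(n[1], h[1]), e(n[2], h[2]), e(n[3], h[3]))
  a$x + a$y + a$z
}

# Even (mirror) extension to twice the size along every axis: imposes
# Neumann-like boundaries on the FFT Poisson solve, so linear phase ramps
# survive unwrapping instead of being aliased into the periodic null space.
mirrorExtend <- function(x) {
  d <- dim(x)
  x[c(seq_len(d[1]), rev(seq_len(d[1]))),
    c(seq_len(d[2]), rev(seq_len(d[2]))),
    c(seq_len(d[3]), rev(seq_len(d[3])))]
}

#' Laplacian phase unwrapping
#'
#' Computes the Laplacian of the true phase from sin/cos of the wrapped input
#' (`cos(phi) L sin(phi) - sin(phi) L cos(phi)`, immune to 2*pi jumps) and
#' inverts it with a spectral Poisson solve on the mirror-extended (even
#' reflection, Neumann-like) domain, so linear phase ramps are recovered
#' rather than aliased away. The global constant is unrecoverable and fixed
#' by a zero-mean convention, consistent with unreferenced susceptibility
#' mapping.
#'
#' The sin/cos Laplacian estimate degrades where phase gradients approach a
#' radian per voxel, so the solve is refined iteratively: the residual
#' between the data and the current estimate is rewrapped (making it small
#' where the estimate is already close), unwrapped with the same Poisson
#' solve, and added back. A few iterations suffice.
#'
#' @param wrapped a [FieldVolume-class] in rad with values in [-pi, pi).
#' @param refineIter residual-refinement iterations (default 4).
#' @return A [FieldVolume-class] of unwrapped phase (rad, zero mean).
#' @export
laplacianUnwrap <- function(wrapped, refineIter = 4L) {
  stopifnot(is(wrapped, "FieldVolume"))
  if (wrapped@units != "rad")
    stop("laplacianUnwrap expects phase in rad")
  d <- dim(wrapped@values)
  lhat <- laplacianHatDims(2L * d, wrapped@grid@voxelSize)
  inv <- 1 / lhat
  inv[1, 1, 1] <- 0 # zero-mean solution
  solveOnce <- function(w) {
    phi <- mirrorExtend(w)
    lap <- function(x) convHat(x, lhat)
    rhs <- cos(phi) * lap(sin(phi)) - sin(phi) * lap(cos(phi))
    convHat(rhs, inv)[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])]
  }
  wrapToPi <- function(x) (x + pi) %% (2 * pi) - pi
  out <- solveOnce(wrapped@values)
  for (i in seq_len(refineIter)) {
    resid <- wrapToPi(wrapped@values - out)
    out <- out + solveOnce(resid)
  }
  out <- out - mean(out)
  fieldVolume(out, wrapped@grid, teMs = wrapped@teMs, b0T = wrapped@b0T,
              units = "rad")
}

#' Variable-kernel SMV background-field removal
#'
#' High-pass filters the field with, at each voxel, the largest spherical
#' kernel (from `r0Mm` down to `rminMm` in `stepMm` decrements) that fits
#' entirely inside the ROI. Voxels where not even the `rminMm` kernel fits
#' are dropped, so the output ROI loses only an `rminMm`-thick shell.
#' Harmonic fields from sources outside the ROI equal their spherical means,
#' so this suppresses them while retaining local dipole fields.
#'
#' @param phi a [FieldVolume-class].
#' @param roi binary/logical ROI array.
#' After subtraction, the high-pass distortion of the retained local fields
#' is undone by deconvolving with the final kernel's complement under a
#' truncated-SVD threshold (frequencies where the complement is below the
#' threshold, i.e. the near-harmonic band, are zeroed rather than
#' amplified); set `deconvolve = FALSE` for the raw high-pass residue.
#'
#' @param r0Mm largest kernel radius (default 40 mm).
#' @param stepMm radius decrement (default: one voxel).
#' @param rminMm smallest (final) kernel radius (default: one voxel), also
#'   the deconvolution kernel.
#' @param deconvolve undo the final kernel's high-pass distortion.
#' @param tsvdThreshold truncation threshold for the deconvolution.
#' @return List with `field` (filtered [FieldVolume-class], zero outside the
#'   eroded ROI) and `roi` (the eroded logical mask).
#' @export
vsmvBackgroundRemoval <- function(phi, roi, r0Mm = 40, stepMm = NULL,
                                  rminMm = NULL, deconvolve = TRUE,
                                  tsvdThreshold = 0.05) {
  stopifnot(is(phi, "FieldVolume"))
  grid <- phi@grid
  vox <- max(grid@voxelSize)
  if (is.null(stepMm)) stepMm <- vox
  if (is.null(rminMm)) rminMm <- vox
  if (!(r0Mm >= rminMm && rminMm >= vox - 1e-9))
    stop("require r0Mm >= rminMm >= one voxel")
  radii <- rev(seq(rminMm, r0Mm, by = stepMm)) # descending
  m <- roi * 1.0
  vals <- phi@values * m
  valsHat <- fftn(vals)
  mhat <- fftn(m)
  out <- array(0, grid@shape)
  assignedR <- array(NA_real_, grid@shape)
  for (r in radii) {
    ker <- makeSMVKernel(grid, r)
    # kernel fits at a voxel if all its mass lies inside the ROI
    occupancy <- reifftn(ker$hat * mhat)
    fits <- roi & occupancy >= 1 - 1e-6
    new <- fits & is.na(assignedR)
    if (!any(new)) next
    filt <- vals - reifftn(ker$hat * valsHat) # (delta - S_r) * phi
    if (deconvolve) {
      comp <- 1 - ker$hat
      inv <- ifelse(Mod(comp) >= tsvdThreshold, 1 / comp, 0)
      filt <- reifftn(inv * fftn(filt * fits))
    }
    out[new] <- filt[new]
    assignedR[new] <- r
  }
  keep <- !is.na(assignedR)
  if (!any(keep))
    stop("ROI too small: the rminMm kernel fits nowhere")
  out[!keep] <- 0
  list(field = fieldVolume(out, grid, teMs = phi@teMs, b0T = phi@b0T,
                           units = phi@units),
       roi = keep)
}

#' Normalise a field map to the TE.B0 = 60 ms.T convention
#'
#' Scales the field by `60 / (TE[ms] * B0[T])` so that a single lambda range
#' transfers across acquisitions with different echo times and field
#' strengths. Unit-tracked: applying it twice is an error.
#'
#' @param phi a [FieldVolume-class] in rad with `teMs` and `b0T` set.
#' @return A [FieldVolume-class] with `units = "normalised"`.
#' @export
normalizeField <- function(phi) {
  stopifnot(is(phi, "FieldVolume"))
  if (phi@units == "normalised")
    stop("field is already normalised; normalizeField cannot be applied twice")
  if (!is.finite(phi@teMs) || !is.finite(phi@b0T) ||
      phi@teMs == 0 || phi@b0T == 0)
    stop("teMs and b0T must be set and nonzero to normalise")
  s <- 60 / (phi@teMs * phi@b0T)
  fieldVolume(phi@values * s, phi@grid, teMs = phi@teMs, b0T = phi@b0T,
              units = "normalised")
}

#' Scale-wise noise weights from the signal magnitude
#'
#' The phase-noise distribution is approximated by the inverse signal
#' magnitude. With `Ahat` the magnitude normalised to ROI mean 1 and
#' `Ahat_l` its SMV-smoothed counterpart (similarly normalised), the
#' composite weight for scale l is `[Ahat^-2 + Ahat_l^-2]^(-1/2)`, zero
#' outside the ROI. Dead (zero-magnitude) voxels get weight 0 with a warning.
#'
#' @param magnitude 3D magnitude array (> 0 on the ROI).
#' @param roi binary/logical ROI.
#' @param smvHat transfer function of the scale's SMV kernel.
#' @return Nonnegative 3D weight array.
#' @export
noiseWeight <- function(magnitude, roi, smvHat) {
  stopifnot3d(magnitude)
  roi <- roi > 0
  dead <- roi & magnitude <= 0
  if (any(dead)) {
    warning(sprintf("%d zero-magnitude voxels inside ROI: weight clamped to 0",
                    sum(dead)))
  }
  ahat <- array(0, dim(magnitude))
  ahat[roi] <- magnitude[roi] / mean(magnitude[roi])
  asm <- smvFilter(magnitude, smvHat, roi = roi)
  ahatl <- array(0, dim(magnitude))
  ahatl[roi] <- asm[roi] / mean(asm[roi])
  w <- array(0, dim(magnitude))
  ok <- roi & ahat > 0 & ahatl > 0
  w[ok] <- (ahat[ok]^-2 + ahatl[ok]^-2)^(-0.5)
  w
}

# The 13 unique (antipodal-collapsed) directions of the 3x3x3 neighbourhood.
secondDiffDirections <- function() {
  dirs <- expand.grid(x = -1:1, y = -1:1, z = -1:1)
  dirs <- dirs[!(dirs$x == 0 & dirs$y == 0 & dirs$z == 0), ]
  keep <- apply(dirs, 1, function(d) {
    nz <- d[d != 0]
    nz[1] > 0
  })
  as.matrix(dirs[keep, ])
}

#' Phase second-difference quality map
#'
#' Per-voxel root-sum-of-squares of second differences
#' `phi(v+d) - 2 phi(v) + phi(v-d)` along the 13 unique directions of the
#' 3x3x3 neighbourhood. Large values flag unreliable phase (noise, flow,
#' unwrapping failures); the reliability masks threshold this map. Boundary
#' voxels use the directions for which both neighbours exist.
#'
#' @param phi 3D phase array or [FieldVolume-class].
#' @param wrapped when TRUE, each first difference is wrapped to [-pi, pi)
#'   before the second difference is formed (for raw wrapped phase).
#' @return Nonnegative 3D array.
#' @export
secondDifferenceMap <- function(phi, wrapped = FALSE) {
  if (is(phi, "FieldVolume")) phi <- phi@values
  stopifnot3d(phi)
  wrapToPi <- function(x) (x + pi) %% (2 * pi) - pi
  dirs <- secondDiffDirections()
  acc <- array(0, dim(phi))
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ]
    fw <- arrShift3(phi, -d) # value at v + d
    bw <- arrShift3(phi, d)  # value at v - d
    if (wrapped) {
      s2 <- wrapToPi(fw - phi) + wrapToPi(bw - phi)
    } else {
      s2 <- fw - 2 * phi + bw
    }
    s2[is.na(s2)] <- 0 # boundary: direction skipped
    acc <- acc + s2^2
  }
  sqrt(acc)
}
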