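# The Laplacian-pyramid scale loop: serial SMV band-pass preconditioning,
# per-scale constrained inversion, and accumulation of the multi-scale
# susceptibility estimate.

#' Snap a radius schedule to the voxel resolution
#'
#' Each requested radius is snapped to the nearest positive multiple of the
#' largest voxel dimension; duplicates after snapping are collapsed with a
#' warning.
#'
#' @param voxelSizeMm numeric(3) voxel size (mm).
#' @param radiiMm requested radii, positive ascending.
#' @return Realised radii (mm).
#' @examples
#' scaleSchedule(c(1, 1, 2), 3) # 4: nearest multiple of 2
#' scaleSchedule(0.8, 2)        # 2.4: 3 voxels
#' @export
scaleSchedule <- function(voxelSizeMm, radiiMm) {
  if (any(radiiMm <= 0) || is.unsorted(radiiMm))
    stop("radii must be positive and ascending")
  m <- max(rep_len(voxelSizeMm, 3L))
  snapped <- pmax(1, floor(radiiMm / m + 0.5)) * m # ties round up
  out <- unique(snapped)
  if (length(out) < length(snapped))
    warning("duplicate radii after snapping to voxel resolution collapsed")
  if (length(out) == 0) stop("empty radius schedule")
  out
}

#' Multi-scale inversion configuration
#'
#' Builds the default four-scale schedule (r = 2, 4, 8, 16 mm) with the
#' morphological prior active on the first scale only and a single shared
#' regularisation weight, or any variant thereof. `lambda` may be a vector
#' (recycled across scales) for the high-fidelity short-range recipes where
#' lambda increases as the maximum radius decreases.
#'
#' @param radiiMm ascending SMV radii (mm); snapped to the voxel grid inside
#'   [runMSDI()].
#' @param lambda consistency weight(s); default 10^2.7.
#' @param edgePriorScales indices of scales using the magnitude edge mask
#'   (default: scale 1 only).
#' @param qPercent base reliability-masking percentile (default 10).
#' @param ... further arguments passed to [scaleSpec()].
#' @return An [MSDIConfig-class].
#' @examples
#' msdiConfig()
#' msdiConfig(radiiMm = 2, lambda = 10^1.6) # VenoMSDI recipe
#' @export
msdiConfig <- function(radiiMm = c(2, 4, 8, 16), lambda = 10^2.7,
                       edgePriorScales = 1L, qPercent = 10, ...) {
  lambda <- rep_len(lambda, length(radiiMm))
  scales <- lapply(seq_along(radiiMm), function(l) {
    scaleSpec(rMm = radiiMm[l], lambda = lambda[l],
              useEdgePrior = l %in% edgePriorScales, qPercent = qPercent,
              ...)
  })
  new("MSDIConfig", scales = scales)
}

#' Run the multi-scale dipole inversion
#'
#' For each pyramid level l = 1..L: re-initialise the field as
#' `phi_l = phi - FH(D F X_{l-1})` (all contributions unaccounted for by
#' previous scales), high-pass filter it with the scale's SMV kernel
#' (in-ROI renormalised, so the mask is never eroded), build the scale's
#' noise weights, reliability mask and (scale 1 only, by default) edge mask,
#' solve the constrained minimisation, and accumulate
#' `X_l = X_{l-1} + X'_l`. The full map is the last cumulative sum; any
#' prefix sum is a high-pass susceptibility map (HPSM).
#'
#' @param phi a [FieldVolume-class] with `units = "normalised"` (see
#'   [normalizeField()]): the background-filtered (or raw) local field.
#' @param magnitude 3D magnitude array.
#' @param roi binary/logical ROI.
#' @param config an [MSDIConfig-class]; radii are snapped to the grid via
#'   [scaleSchedule()].
#' @param verbose print per-scale progress.
#' @return An [MSDIResult-class].
#' @export
runMSDI <- function(phi, magnitude, roi, config = msdiConfig(),
                    verbose = FALSE) {
  stopifnot(is(phi, "FieldVolume"))
  if (phi@units != "rad" && phi@units != "normalised")
    stop("unknown field units")
  if (phi@units == "rad")
    stop("field must be normalised first (see normalizeField())")
  grid <- phi@grid
  stopifnot3d(magnitude)
  if (!sameDim(magnitude, phi@values) || !sameDim(roi * 1.0, phi@values))
    stop("magnitude/roi must match the field grid")
  roi <- roi > 0
  if (!any(roi)) stop("ROI is empty")
  radii0 <- vapply(config@scales, function(s) s@rMm, numeric(1))
  m <- max(grid@voxelSize)
  snapped <- pmax(1, floor(radii0 / m + 0.5)) * m
  keepIdx <- !duplicated(snapped)
  if (any(!keepIdx))
    warning("duplicate radii after snapping to voxel resolution collapsed")
  radii <- snapped[keepIdx]
  specs <- config@scales[keepIdx]
  # normalised fields behave as TE.B0 = 60 ms.T
  kernels <- kernelSet(grid, radiiMm = radii, teMs = 60, b0T = 1)
  phiVals <- phi@values
  sdm <- secondDifferenceMap(phiVals)
  em <- NULL
  X <- array(0, grid@shape)
  results <- vector("list", length(radii))
  for (l in seq_along(radii)) {
    spec <- specs[[l]]
    spec@rMm <- radii[l]
    phiL <- phiVals - kernels@chiToPhase * forwardField(X, kernels)
    phiHp <- smvFilter(phiL, kernels@smvHat[[l]], roi = roi,
                       highpass = TRUE)
    aprime <- noiseWeight(magnitude, roi, kernels@smvHat[[l]])
    qmask <- reliabilityMask(sdm, roi, l, qPercent = spec@qPercent,
                             radiiMm = radii)
    emaskL <- NULL
    if (spec@useEdgePrior) {
      if (is.null(em)) em <- edgeMask(magnitude, roi)
      emaskL <- em
    }
    if (verbose)
      message(sprintf("scale %d: r = %g mm, lambda = 10^%.3g", l, radii[l],
                      log10(spec@lambda)))
    res <- tryCatch(
      solveScale(phiHp, aprime, qmask, emaskL, kernels, l, spec),
      error = function(e) stop(sprintf("scale %d failed: %s", l,
                                       conditionMessage(e)), call. = FALSE))
    X <- X + res@chiDelta
    res@chiCum <- X
    results[[l]] <- res
  }
  new("MSDIResult", scales = results, config = config, grid = grid,
      roi = roi * 1.0)
}

#' Extract a susceptibility map from an inversion result
#'
#' @param result an [MSDIResult-class].
#' @param scale pyramid level (default: last, the full-scale map).
#' @return 3D susceptibility array (ppm), the cumulative sum up to `scale`.
#' @export
susceptibilityMap <- function(result, scale = length(result@scales)) {
  stopifnot(is(result, "MSDIResult"))
  result@scales[[scale]]@chiCum
}

#' High-pass susceptibility map (HPSM)
#'
#' The cumulative susceptibility over scales with SMV radius up to
#' `rMaxMm`: the inversion of short-range dipole fields only, which carries
#' fine anatomical/vascular detail and is insensitive to long-range
#' background contamination.
#'
#' @param result an [MSDIResult-class].
#' @param rMaxMm largest SMV radius to include (default 2 mm).
#' @return 3D susceptibility array (ppm).
#' @export
hpsm <- function(result, rMaxMm = 2) {
  stopifnot(is(result, "MSDIResult"))
  r <- vapply(result@scales, function(s) s@rMm, numeric(1))
  keep <- which(r <= rMaxMm + 1e-9)
  if (length(keep) == 0)
    stop("no scale with radius <= rMaxMm")
  result@scales[[max(keep)]]@chiCum
}

#' Per-scale cost trajectories
#'
#' @param result an [MSDIResult-class].
#' @return data.frame with columns scale, iteration, fidelity, regulariser.
#' @export
costHistory <- function(result) {
  stopifnot(is(result, "MSDIResult"))
  do.call(rbind, lapply(result@scales, function(s) {
    n <- nrow(s@costHistory)
    data.frame(scale = rep(s@scaleIndex, n), iteration = seq_len(n),
               fidelity = s@costHistory[, "fidelity"],
               regulariser = s@costHistory[, "regulariser"])
  }))
}
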