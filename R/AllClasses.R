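#' @import methods
NULL

#' Voxel grid geometry
#'
#' Describes the regular 3D lattice on which all volumes live: array shape,
#' voxel edge lengths in millimetres, and the unit vector of the main field
#' (B0) direction, which orients the dipole kernel. By convention B0 points
#' along the third array axis unless stated otherwise; oblique acquisitions
#' are handled by rotating `b0Dir`, not by resampling.
#'
#' @slot shape integer(3), array dimensions (each >= 2; inversions need >= 8).
#' @slot voxelSize numeric(3), voxel edge lengths in mm.
#' @slot b0Dir numeric(3), unit vector of the static field direction.
#' @export
setClass("VoxelGrid",
  representation(shape = "integer", voxelSize = "numeric", b0Dir = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shape) != 3L || any(object@shape < 2L))
      msg <- c(msg, "shape must be 3 integers, all >= 2")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      msg <- c(msg, "voxelSize must be 3 positive reals (mm)")
    if (length(object@b0Dir) != 3L ||
        abs(sqrt(sum(object@b0Dir^2)) - 1) > 1e-9)
      msg <- c(msg, "b0Dir must be a unit 3-vector (|b0Dir| = 1 within 1e-9)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a voxel grid
#'
#' @param shape integer(3) array dimensions.
#' @param voxelSize numeric(3) voxel size in mm (scalar recycled).
#' @param b0Dir main-field direction; normalised to unit length.
#' @return A [VoxelGrid-class] object.
#' @examples
#' voxelGrid(c(64, 64, 64), 1)
#' @export
voxelGrid <- function(shape, voxelSize = 1, b0Dir = c(0, 0, 1)) {
  voxelSize <- rep_len(as.numeric(voxelSize), 3L)
  nb <- sqrt(sum(b0Dir^2))
  if (nb == 0) stop("b0Dir must be nonzero")
  new("VoxelGrid", shape = as.integer(shape), voxelSize = voxelSize,
      b0Dir = as.numeric(b0Dir) / nb)
}

#' Field volume with unit tracking
#'
#' A scalar 3D phase/field map together with its grid, units and the
#' acquisition constants needed to convert susceptibility (ppm) to phase
#' (rad). `units` is `"rad"` for raw (possibly wrapped) phase and
#' `"normalised"` once the TE.B0 = 60 ms.T harmonisation has been applied.
#'
#' @slot values 3D numeric array.
#' @slot units `"rad"` or `"normalised"`.
#' @slot grid a [VoxelGrid-class].
#' @slot teMs echo time in ms.
#' @slot b0T field strength in Tesla.
#' @export
setClass("FieldVolume",
  representation(values = "array", units = "character", grid = "VoxelGrid",
                 teMs = "numeric", b0T = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@values), as.integer(object@grid@shape)))
      msg <- c(msg, "values dimensions must match grid shape")
    if (!object@units %in% c("rad", "normalised"))
      msg <- c(msg, "units must be 'rad' or 'normalised'")
    if (length(object@teMs) != 1L || length(object@b0T) != 1L)
      msg <- c(msg, "teMs and b0T must be scalars")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a field volume
#'
#' @param values 3D numeric array (phase in rad, or a normalised field).
#' @param grid a [VoxelGrid-class].
#' @param teMs echo time (ms).
#' @param b0T field strength (T).
#' @param units `"rad"` (default) or `"normalised"`.
#' @return A [FieldVolume-class].
#' @export
fieldVolume <- function(values, grid, teMs = NA_real_, b0T = NA_real_,
                        units = "rad") {
  stopifnot3d(values)
  new("FieldVolume", values = values, units = units, grid = grid,
      teMs = as.numeric(teMs), b0T = as.numeric(b0T))
}

#' @describeIn FieldVolume-class numeric array of field values.
#' @param x a `FieldVolume`.
#' @export
fieldValues <- function(x) x@values

#' @describeIn FieldVolume-class units string.
#' @export
fieldUnits <- function(x) x@units

#' Frequency-domain kernel set
#'
#' Holds the dipole kernel D on the grid's frequency lattice, the per-scale
#' SMV (spherical mean value) kernels S_l as transfer functions together with
#' their high-pass complements (1 - F(S_l)), and the susceptibility-to-phase
#' scaling constant (rad per ppm).
#'
#' @slot grid the [VoxelGrid-class] the kernels were built on.
#' @slot dipole real 3D array, D(k) = 1/3 - (k.b0)^2/|k|^2 with D(0) = 0.
#' @slot smvHat list of complex transfer functions F(S_l), one per scale.
#' @slot radiiMm realised SMV radii in mm, one per scale.
#' @slot chiToPhase scalar, 2*pi*gammabar*B0*TE*1e-6 in rad/ppm.
#' @export
setClass("KernelSet",
  representation(grid = "VoxelGrid", dipole = "array", smvHat = "list",
                 radiiMm = "numeric", chiToPhase = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@dipole), as.integer(object@grid@shape)))
      msg <- c(msg, "dipole dimensions must match grid shape")
    if (abs(object@dipole[1, 1, 1]) > 1e-12)
      msg <- c(msg, "dipole kernel must vanish at zero frequency")
    if (length(object@smvHat) != length(object@radiiMm))
      msg <- c(msg, "one SMV kernel per radius required")
    for (h in object@smvHat) {
      if (abs(Re(h[1, 1, 1]) - 1) > 1e-9)
        msg <- c(msg, "SMV kernels must sum to 1 (complement zero at DC)")
    }
    if (is.null(msg)) TRUE else msg
  })

#' Per-scale inversion settings
#'
#' Hyperparameters for one pyramid level: SMV radius, regularisation weight,
#' whether the morphological (edge) prior is active, the MERIT threshold f,
#' the phase-reliability percentile q, the L1 smoothing epsilon, and solver
#' tolerances.
#'
#' @slot rMm SMV kernel radius (mm).
#' @slot lambda positive consistency weight (multiplies the data term).
#' @slot useEdgePrior logical, magnitude edge mask on the regulariser.
#' @slot meritF residual threshold f for MERIT reweighting (default 6).
#' @slot qPercent base percentile q for reliability masking (default 10).
#' @slot epsilon L1 weak-derivative smoothing (default 1e-6).
#' @slot cgTol conjugate-gradient relative tolerance (default 0.1).
#' @slot outerTol quasi-Newton relative update tolerance (default 0.1).
#' @slot maxOuter maximum outer iterations (default 10).
#' @slot maxCg maximum CG iterations per outer step (default 100).
#' @export
setClass("ScaleSpec",
  representation(rMm = "numeric", lambda = "numeric",
                 useEdgePrior = "logical", meritF = "numeric",
                 qPercent = "numeric", epsilon = "numeric", cgTol = "numeric",
                 outerTol = "numeric", maxOuter = "integer",
                 maxCg = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
    if (object@qPercent < 0 || object@qPercent > 100)
      msg <- c(msg, "qPercent must be in [0, 100]")
    if (object@epsilon <= 0) msg <- c(msg, "epsilon must be > 0")
    if (object@rMm <= 0) msg <- c(msg, "rMm must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a per-scale spec
#'
#' Defaults follow the reference recipe: f = 6, q = 10, e = 1e-6,
#' CG tolerance 0.1, outer tolerance 0.1.
#'
#' @param rMm SMV radius in mm.
#' @param lambda consistency weight (default 10^2.7, the L-curve optimum for
#'   the normalised-field convention).
#' @param useEdgePrior apply the magnitude edge mask at this scale.
#' @param meritF,qPercent,epsilon,cgTol,outerTol,maxOuter,maxCg see slots.
#' @return A [ScaleSpec-class].
#' @export
scaleSpec <- function(rMm, lambda = 10^2.7, useEdgePrior = FALSE,
                      meritF = 6, qPercent = 10, epsilon = 1e-6,
                      cgTol = 0.1, outerTol = 0.1, maxOuter = 10L,
                      maxCg = 100L) {
  new("ScaleSpec", rMm = rMm, lambda = lambda, useEdgePrior = useEdgePrior,
      meritF = meritF, qPercent = qPercent, epsilon = epsilon, cgTol = cgTol,
      outerTol = outerTol, maxOuter = as.integer(maxOuter),
      maxCg = as.integer(maxCg))
}

#' Multi-scale inversion configuration
#'
#' An ordered list of [ScaleSpec-class] levels with strictly increasing SMV
#' radii. The default schedule is four scales at r = 2, 4, 8, 16 mm with the
#' morphological prior active on the first (2 mm) scale only and a single
#' shared lambda.
#'
#' @slot scales list of `ScaleSpec`, radii strictly increasing.
#' @export
setClass("MSDIConfig",
  representation(scales = "list"),
  validity = function(object) {
    if (length(object@scales) < 1L) return("at least one scale required")
    if (!all(vapply(object@scales, is, TRUE, class2 = "ScaleSpec")))
      return("scales must be ScaleSpec objects")
    r <- vapply(object@scales, function(s) s@rMm, numeric(1))
    if (any(diff(r) <= 0)) return("scale radii must be strictly increasing")
    TRUE
  })

#' Result of one pyramid scale
#'
#' @slot scaleIndex 1-based pyramid level.
#' @slot rMm realised SMV radius (mm).
#' @slot chiDelta per-scale susceptibility increment (ppm).
#' @slot chiCum cumulative susceptibility up to this scale (ppm).
#' @slot weightsFinal final data-fidelity weights after MERIT.
#' @slot qmask binary phase-reliability mask used at this scale.
#' @slot costHistory matrix with columns `fidelity` and `regulariser`.
#' @slot converged logical, outer loop reached its tolerance.
#' @export
setClass("ScaleResult",
  representation(scaleIndex = "integer", rMm = "numeric",
                 chiDelta = "array", chiCum = "array",
                 weightsFinal = "array", qmask = "array",
                 costHistory = "matrix", converged = "logical"))

#' Full multi-scale inversion result
#'
#' @slot scales list of [ScaleResult-class], finest to coarsest.
#' @slot config the [MSDIConfig-class] used.
#' @slot grid the [VoxelGrid-class].
#' @slot roi binary ROI the inversion was weighted on.
#' @export
setClass("MSDIResult",
  representation(scales = "list", config = "MSDIConfig", grid = "VoxelGrid",
                 roi = "array"))

#' SWI weighting mask
#'
#' Linear ramp weights derived from a high-pass susceptibility map: 1 for
#' diamagnetic/zero susceptibility, falling linearly to 0 at the critical
#' value c, and 0 above it.
#'
#' @slot values 3D array in [0, 1].
#' @slot criticalValuePpm the critical susceptibility c (ppm).
#' @slot power exponent applied on magnitude weighting (default 4).
#' @export
setClass("SWIWeights",
  representation(values = "array", criticalValuePpm = "numeric",
                 power = "integer"),
  validity = function(object) {
    if (any(object@values < 0 | object@values > 1))
      return("weights must lie in [0, 1]")
    TRUE
  })

#' L-curve analysis result
#'
#' @slot points data.frame with columns lambda, logFidelity, logRegulariser.
#' @slot curvature per-point curvature of the log-log curve.
#' @slot optimalLambda lambda at maximum curvature (NA when no corner).
#' @slot noCorner logical, curve is collinear (no usable corner).
#' @export
setClass("LCurve",
  representation(points = "data.frame", curvature = "numeric",
                 optimalLambda = "numeric", noCorner = "logical"))

#' Synthetic phantom specification
#'
#' Describes a piecewise-constant susceptibility scene: geometric objects
#' (spheres, ellipsoids, boxes, cylinders) inside a spherical ROI, point
#' dipole background sources strictly outside the ROI, and the acquisition
#' constants/noise level used to simulate the measured data.
#'
#' @slot grid a [VoxelGrid-class].
#' @slot objects list of lists with fields `shape` (sphere, ellipsoid, box,
#'   cylinder), `centre` (mm, relative to volume centre), `size` (mm),
#'   `chiPpm`, plus `axis`/`length` for cylinders.
#' @slot backgroundSources list of lists with `position` (mm, relative to
#'   volume centre) and `moment` (ppm mm^3 equivalent dipole strength).
#' @slot roiRadiusMm radius of the spherical ROI (mm).
#' @slot snr signal-to-noise ratio of the simulated magnitude (Inf = none).
#' @slot teMs,b0T acquisition constants.
#' @slot seed RNG seed for the noise draw.
#' @export
setClass("PhantomSpec",
  representation(grid = "VoxelGrid", objects = "list",
                 backgroundSources = "list", roiRadiusMm = "numeric",
                 snr = "numeric", teMs = "numeric", b0T = "numeric",
                 seed = "integer"))

setMethod("show", "VoxelGrid", function(object) {
  cat(sprintf("VoxelGrid %s, voxel %s mm, B0 dir (%.3g, %.3g, %.3g)\n",
              paste(object@shape, collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = "x"),
              object@b0Dir[1], object@b0Dir[2], object@b0Dir[3]))
})

setMethod("show", "FieldVolume", function(object) {
  cat(sprintf("FieldVolume [%s] %s, TE %.3g ms, B0 %.3g T, range [%.3g, %.3g]\n",
              object@units, paste(dim(object@values), collapse = "x"),
              object@teMs, object@b0T, min(object@values),
              max(object@values)))
})

setMethod("show", "KernelSet", function(object) {
  cat(sprintf("KernelSet on %s grid; SMV radii %s mm; chiToPhase %.4g rad/ppm\n",
              paste(object@grid@shape, collapse = "x"),
              paste(signif(object@radiiMm, 4), collapse = ", "),
              object@chiToPhase))
})

setMethod("show", "MSDIConfig", function(object) {
  r <- vapply(object@scales, function(s) s@rMm, numeric(1))
  l <- vapply(object@scales, function(s) s@lambda, numeric(1))
  e <- vapply(object@scales, function(s) s@useEdgePrior, logical(1))
  cat(sprintf("MSDIConfig: %d scales\n", length(r)))
  for (i in seq_along(r))
    cat(sprintf("  scale %d: r = %g mm, lambda = 10^%.3g, edge prior %s\n",
                i, r[i], log10(l[i]), if (e[i]) "on" else "off"))
})

setMethod("show", "MSDIResult", function(object) {
  cat(sprintf("MSDIResult: %d scales on %s grid\n", length(object@scales),
              paste(object@grid@shape, collapse = "x")))
  for (s in object@scales)
    cat(sprintf("  scale %d (r = %g mm): %d outer iterations, %s\n",
                s@scaleIndex, s@rMm, nrow(s@costHistory),
                if (s@converged) "converged" else "max iterations"))
})

setMethod("show", "LCurve", function(object) {
  if (object@noCorner) {
    cat("LCurve: no corner (collinear points)\n")
  } else {
    cat(sprintf("LCurve: %d points, optimal lambda = 10^%.3g\n",
                nrow(object@points), log10(object@optimalLambda)))
  }
})
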