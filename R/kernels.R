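# Frequency-domain dipole and spherical-mean-value kernels, and the linear
# forward field model they define.

# Gyromagnetic ratio of the proton, MHz/T.
GAMMA_BAR_MHZ_T <- 42.576

#' Susceptibility-to-phase scaling constant
#'
#' The factor converting a dipole-convolved susceptibility distribution (ppm)
#' into phase (rad): 2*pi*gammabar*B0*TE*1e-6 with gammabar = 42.576 MHz/T.
#' After [normalizeField()] all fields behave as if TE.B0 = 60 ms.T, for
#' which this constant is ~16.05 rad/ppm.
#'
#' @param teMs echo time in ms.
#' @param b0T field strength in Tesla.
#' @return Scalar, rad per ppm.
#' @examples
#' chiToPhaseFactor(20, 3) # TE.B0 = 60 ms.T
#' @export
chiToPhaseFactor <- function(teMs, b0T) {
  2 * pi * GAMMA_BAR_MHZ_T * 1e6 * b0T * (teMs * 1e-3) * 1e-6
}

#' Frequency-domain dipole kernel
#'
#' D(k) = 1/3 - (k.b0)^2/|k|^2 on the grid's discrete frequency lattice, with
#' D(0) = 0 so that solutions are unreferenced (zero mean). The kernel
#' vanishes on the magic-angle cone (k.b0)^2 = |k|^2/3, which is what makes
#' dipole inversion ill-posed.
#'
#' @param grid a [VoxelGrid-class].
#' @return Real 3D array of dipole coefficients (dimensionless).
#' @examples
#' D <- makeDipoleKernel(voxelGrid(c(16, 16, 16), 1))
#' D[1, 1, 1] # zero at DC
#' @export
makeDipoleKernel <- function(grid) {
  n <- grid@shape
  if (any(n < 2L)) stop("degenerate grid: all dimensions must be >= 2")
  k <- axisArrays(fftFreq(n[1], grid@voxelSize[1]),
                  fftFreq(n[2], grid@voxelSize[2]),
                  fftFreq(n[3], grid@voxelSize[3]))
  kz <- k$x * grid@b0Dir[1] + k$y * grid@b0Dir[2] + k$z * grid@b0Dir[3]
  k2 <- k$x^2 + k$y^2 + k$z^2
  D <- 1 / 3 - kz^2 / k2
  D[k2 == 0] <- 0
  D
}

#' Spherical-mean-value kernel
#'
#' Rasterises a sphere of the given radius (a voxel belongs to the kernel if
#' its centre lies within the radius; anisotropic voxels honoured),
#' normalises it to unit sum, and returns the spatial kernel together with
#' its transfer function and high-pass complement 1 - F(S).
#'
#' @param grid a [VoxelGrid-class].
#' @param radiusMm kernel radius in mm; must be at least the largest voxel
#'   dimension (a smaller radius would degenerate to a delta).
#' @return List with elements `spatial` (real array summing to 1), `hat`
#'   (complex transfer function) and `complementHat` (1 - hat, zero at DC).
#' @examples
#' s <- makeSMVKernel(voxelGrid(c(16, 16, 16), 1), 2)
#' sum(s$spatial)
#' @export
makeSMVKernel <- function(grid, radiusMm) {
  if (radiusMm < max(grid@voxelSize))
    stop("SMV radius smaller than one voxel: filter undefined")
  n <- grid@shape
  x <- axisArrays(wrapCoord(n[1], grid@voxelSize[1]),
                  wrapCoord(n[2], grid@voxelSize[2]),
                  wrapCoord(n[3], grid@voxelSize[3]))
  d2 <- x$x^2 + x$y^2 + x$z^2
  ker <- (d2 <= radiusMm^2) * 1.0
  ker <- ker / sum(ker)
  hat <- fftn(ker)
  list(spatial = ker, hat = hat, complementHat = 1 - hat)
}

#' Build the full kernel set for a grid
#'
#' @param grid a [VoxelGrid-class].
#' @param radiiMm SMV radii in mm, ascending (default 2, 4, 8, 16).
#' @param teMs,b0T acquisition constants fixing the chi-to-phase scaling;
#'   the defaults give TE.B0 = 60 ms.T, the normalised-field convention.
#' @return A [KernelSet-class].
#' @export
kernelSet <- function(grid, radiiMm = c(2, 4, 8, 16), teMs = 20, b0T = 3) {
  if (any(grid@shape < 8L))
    warning("grids smaller than 8 voxels per axis are unreliable for inversion")
  smv <- lapply(radiiMm, function(r) makeSMVKernel(grid, r)$hat)
  new("KernelSet", grid = grid, dipole = makeDipoleKernel(grid),
      smvHat = smv, radiiMm = as.numeric(radiiMm),
      chiToPhase = chiToPhaseFactor(teMs, b0T))
}

#' @describeIn kernelSet high-pass complement transfer function of scale `l`.
#' @param kernels a [KernelSet-class].
#' @param l scale index.
#' @export
smvComplement <- function(kernels, l) 1 - kernels@smvHat[[l]]

#' Linear forward field model
#'
#' Applies the dipole convolution in the frequency domain:
#' `FH(D F chi)`, optionally band-limited by the high-pass SMV complement of
#' one scale (`FH(S~_l D F chi)`). The result is a field in ppm; multiply by
#' `chiToPhase` for radians.
#'
#' @param chi 3D susceptibility array (ppm).
#' @param kernels a [KernelSet-class] on the same grid.
#' @param highpassScale optional scale index l; when given, the field is
#'   high-pass filtered with the complement of S_l.
#' @return 3D field array (ppm units).
#' @export
forwardField <- function(chi, kernels, highpassScale = NULL) {
  stopifnot3d(chi)
  if (!identical(dim(chi), as.integer(kernels@grid@shape)))
    stop("grid mismatch between chi and kernels")
  op <- kernels@dipole
  if (!is.null(highpassScale)) op <- op * smvComplement(kernels, highpassScale)
  reifftn(op * fftn(chi))
}

#' Adjoint of the forward field model
#'
#' Exact adjoint of [forwardField()] in the real Euclidean inner product
#' (conjugated transfer function). For the real, even dipole/SMV kernels this
#' coincides with the forward operator up to FFT round-off; the explicit
#' conjugation keeps the CG normal equations symmetric to machine precision.
#'
#' @inheritParams forwardField
#' @param y 3D field array.
#' @return 3D array.
#' @export
forwardFieldAdjoint <- function(y, kernels, highpassScale = NULL) {
  stopifnot3d(y)
  if (!identical(dim(y), as.integer(kernels@grid@shape)))
    stop("grid mismatch between y and kernels")
  op <- kernels@dipole
  if (!is.null(highpassScale)) op <- op * smvComplement(kernels, highpassScale)
  reifftn(Conj(op) * fftn(y))
}

#' SMV filtering with optional in-ROI renormalisation
#'
#' Low-pass (spherical mean) or high-pass (value minus spherical mean)
#' filtering. When a ROI is supplied, the kernel mass is renormalised to the
#' portion inside the ROI so boundary voxels use an unbiased in-ROI mean and
#' the mask is not eroded.
#'
#' @param vol 3D array.
#' @param hat SMV transfer function (from [makeSMVKernel()] or a
#'   [KernelSet-class] slot).
#' @param roi optional binary array; output is zero outside it.
#' @param highpass return `vol - mean` instead of the mean.
#' @return Filtered 3D array.
#' @export
smvFilter <- function(vol, hat, roi = NULL, highpass = FALSE) {
  stopifnot3d(vol)
  if (is.null(roi)) {
    lo <- convHat(vol, hat)
  } else {
    m <- roi * 1.0
    den <- convHat(m, hat)
    lo <- array(0, dim(vol))
    inside <- m > 0 & den > 1e-9
    lo[inside] <- (convHat(vol * m, hat))[inside] / den[inside]
  }
  out <- if (highpass) vol - lo else lo
  if (!is.null(roi)) out <- out * (roi * 1.0)
  out
}
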