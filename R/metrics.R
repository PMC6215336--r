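# Reconstruction quality metrics (RMSE, HFEN, 1-SSIM, ROI error) and L-curve
# regularisation parameter selection.

#' Percent root-mean-square error
#'
#' `100 * ||x - ref||_2 / ||ref||_2` over the ROI.
#'
#' @param x,ref 3D arrays.
#' @param roi binary/logical ROI (default: whole volume).
#' @return Scalar percentage.
#' @export
rmsePercent <- function(x, ref, roi = NULL) {
  stopifnot3d(x); stopifnot3d(ref)
  if (!sameDim(x, ref)) stop("grid mismatch")
  if (is.null(roi)) roi <- array(TRUE, dim(x))
  roi <- roi > 0
  100 * sqrt(sum((x[roi] - ref[roi])^2)) / sqrt(sum(ref[roi]^2))
}

# 3D Laplacian-of-Gaussian kernel, zero-sum, given taps and sigma (voxels).
logKernel3 <- function(taps = 15L, sigma = 1.5) {
  h <- (taps - 1) / 2
  ax <- -h:h
  co <- axisArrays(ax, ax, ax)
  r2 <- co$x^2 + co$y^2 + co$z^2
  g <- exp(-r2 / (2 * sigma^2))
  k <- (r2 - 3 * sigma^2) / sigma^4 * g
  k - mean(k) # exact zero sum: annihilates DC
}

# Circular convolution of a volume with a small origin-centred kernel.
convKernel <- function(vol, kernel) {
  d <- dim(vol)
  kd <- dim(kernel)
  if (any(kd > d)) stop("kernel larger than volume")
  emb <- array(0, d)
  emb[1:kd[1], 1:kd[2], 1:kd[3]] <- kernel
  # centre the kernel on the origin voxel (wrap-around)
  h <- (kd - 1) / 2
  for (ax in 1:3) {
    idx <- lapply(d, seq_len)
    n <- d[ax]
    sft <- ((seq_len(n) - 1 + h[ax]) %% n) + 1
    idx[[ax]] <- sft
    emb <- emb[idx[[1]], idx[[2]], idx[[3]]]
  }
  convHat(vol, fftn(emb))
}

#' Percent high-frequency error norm (HFEN)
#'
#' RMSE percentage computed after Laplacian-of-Gaussian filtering of both
#' volumes (15^3 taps, sigma = 1.5 voxels): sensitive to fine-structure
#' errors, blind to constant offsets.
#'
#' @inheritParams rmsePercent
#' @param taps,sigma LoG kernel parameters.
#' @return Scalar percentage.
#' @export
hfenPercent <- function(x, ref, roi = NULL, taps = 15L, sigma = 1.5) {
  stopifnot3d(x); stopifnot3d(ref)
  if (!sameDim(x, ref)) stop("grid mismatch")
  k <- logKernel3(taps, sigma)
  rmsePercent(convKernel(x, k), convKernel(ref, k), roi)
}

# Gaussian window transfer function for SSIM filtering.
gaussHat <- function(d, taps = 11L, sigma = 1.5) {
  h <- (taps - 1) / 2
  ax <- -h:h
  co <- axisArrays(ax, ax, ax)
  g <- exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * sigma^2))
  g <- g / sum(g)
  emb <- array(0, d)
  emb[1:taps, 1:taps, 1:taps] <- g
  for (axn in 1:3) {
    idx <- lapply(d, seq_len)
    n <- d[axn]
    idx[[axn]] <- ((seq_len(n) - 1 + h) %% n) + 1
    emb <- emb[idx[[1]], idx[[2]], idx[[3]]]
  }
  fftn(emb)
}

#' Structural dissimilarity (1 - SSIM)
#'
#' One minus the mean structural similarity index over the ROI, computed with
#' a 3D Gaussian window (sigma = 1.5 voxels, 11^3 taps), constants K1 = 0.01
#' and K2 = 0.03, and dynamic range set to the reference's max - min over the
#' ROI. Invariant to a joint affine rescaling of both inputs. Like any
#' SSIM-derived score on quantitative maps, it rewards smoothness and should
#' be interpreted with caution.
#'
#' @inheritParams rmsePercent
#' @param k1,k2 SSIM stabilisation constants.
#' @param sigma Gaussian window sigma in voxels.
#' @param taps window size.
#' @return Scalar in [0, 2].
#' @export
oneMinusSSIM <- function(x, ref, roi = NULL, k1 = 0.01, k2 = 0.03,
                         sigma = 1.5, taps = 11L) {
  stopifnot3d(x); stopifnot3d(ref)
  if (!sameDim(x, ref)) stop("grid mismatch")
  if (is.null(roi)) roi <- array(TRUE, dim(x))
  roi <- roi > 0
  L <- max(ref[roi]) - min(ref[roi])
  if (L == 0) L <- .Machine$double.eps
  c1 <- (k1 * L)^2
  c2 <- (k2 * L)^2
  gh <- gaussHat(dim(x), taps, sigma)
  f <- function(v) convHat(v, gh)
  mx <- f(x); mr <- f(ref)
  vx <- f(x^2) - mx^2
  vr <- f(ref^2) - mr^2
  cov <- f(x * ref) - mx * mr
  ssim <- ((2 * mx * mr + c1) * (2 * cov + c2)) /
    ((mx^2 + mr^2 + c1) * (vx + vr + c2))
  1 - mean(ssim[roi])
}

#' Mean absolute multi-ROI error
#'
#' Mean over labelled regions of the absolute difference between the region
#' means of the two volumes.
#'
#' @param x,ref 3D arrays (ppm).
#' @param labels integer label array; 0 = background, each positive value one
#'   region.
#' @return Scalar (same units as the inputs).
#' @export
roiError <- function(x, ref, labels) {
  stopifnot3d(x); stopifnot3d(ref)
  if (!sameDim(x, labels)) stop("grid mismatch")
  ids <- sort(unique(labels[labels > 0]))
  if (length(ids) == 0) stop("no labelled regions")
  errs <- vapply(ids, function(i) {
    sel <- labels == i
    abs(mean(x[sel]) - mean(ref[sel]))
  }, numeric(1))
  mean(errs)
}

#' L-curve regularisation parameter selection
#'
#' Given data-fidelity and regulariser costs over a log-spaced lambda grid,
#' computes the curvature of the (log fidelity, log regulariser) curve via
#' second-order finite differences on a smoothing-spline fit (falling back to
#' raw differences for short grids) and returns the lambda of maximum
#' curvature magnitude: the L-curve "corner" balancing the two costs. When
#' the points are collinear in log-log space the curvature vanishes and the
#' no-corner flag is set.
#'
#' @param lambdas strictly increasing lambda grid (>= 5 points, log-spaced).
#' @param fidelityCosts,regCosts positive cost values per lambda.
#' @return An [LCurve-class].
#' @export
lcurveSelect <- function(lambdas, fidelityCosts, regCosts) {
  n <- length(lambdas)
  if (n < 5) stop("at least 5 lambda points required")
  if (any(diff(lambdas) <= 0)) stop("lambdas must be strictly increasing")
  if (any(fidelityCosts <= 0) || any(regCosts <= 0))
    stop("costs must be positive for log-log analysis")
  t <- log10(lambdas)
  xi <- log(fidelityCosts)
  eta <- log(regCosts)
  derivs <- function(y) {
    fit <- tryCatch(
      stats::smooth.spline(t, y, df = max(4, min(n - 2, ceiling(n / 2))),
                           all.knots = TRUE),
      error = function(e) NULL)
    if (is.null(fit)) {
      # central differences on the raw points
      d1 <- numeric(n)
      d1[1] <- (y[2] - y[1]) / (t[2] - t[1])
      d1[n] <- (y[n] - y[n - 1]) / (t[n] - t[n - 1])
      d1[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
      d2 <- numeric(n)
      d2[2:(n - 1)] <- (d1[3:n] - d1[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)])
      d2[1] <- d2[2]; d2[n] <- d2[n - 1]
      list(d1 = d1, d2 = d2)
    } else {
      list(d1 = stats::predict(fit, t, deriv = 1)$y,
           d2 = stats::predict(fit, t, deriv = 2)$y)
    }
  }
  dx <- derivs(xi)
  dy <- derivs(eta)
  kappa <- (dx$d1 * dy$d2 - dy$d1 * dx$d2) /
    (dx$d1^2 + dy$d1^2)^1.5
  kappa[!is.finite(kappa)] <- 0
  noCorner <- max(abs(kappa)) < 1e-6
  opt <- if (noCorner) NA_real_ else lambdas[which.max(abs(kappa))]
  new("LCurve",
      points = data.frame(lambda = lambdas, logFidelity = xi,
                          logRegulariser = eta),
      curvature = kappa, optimalLambda = opt, noCorner = noCorner)
}
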