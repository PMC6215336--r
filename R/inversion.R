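# Single-scale constrained dipole deconvolution: the nonlinear
# morphology-constrained minimisation
#   argmin_X  lambda ||Q W (exp(i C X) - exp(i phi'))||_2^2 + ||M grad X||_1
# solved by a quasi-Newton fixed-point scheme (first-order linearisation of
# the complex exponential, iteratively reweighted L1, nested CG solves) with
# MERIT residual down-weighting between outer iterations.

# Forward differences along one axis, zero gradient on the trailing face,
# scaled by voxel size. The matched adjoint keeps both operators DC-blind,
# which is what makes unreferenced (zero-mean) solutions fall out of CG.
gradAxis <- function(x, axis, h) {
  d <- dim(x)
  n <- d[axis]
  idx <- lapply(d, seq_len)
  a <- idx; b <- idx
  a[[axis]] <- c(2:n, n)
  g <- (x[a[[1]], a[[2]], a[[3]]] - x) / h
  last <- idx; last[[axis]] <- n
  g[last[[1]], last[[2]], last[[3]]] <- 0
  g
}

gradAxisAdjoint <- function(y, axis, h) {
  d <- dim(y)
  n <- d[axis]
  idx <- lapply(d, seq_len)
  prev <- idx
  prev[[axis]] <- c(1, 1:(n - 1))
  out <- (y[prev[[1]], prev[[2]], prev[[3]]] - y) / h
  first <- idx; first[[axis]] <- 1
  out[first[[1]], first[[2]], first[[3]]] <-
    -y[first[[1]], first[[2]], first[[3]]] / h
  last <- idx; last[[axis]] <- n
  prevLast <- idx; prevLast[[axis]] <- n - 1
  out[last[[1]], last[[2]], last[[3]]] <-
    y[prevLast[[1]], prevLast[[2]], prevLast[[3]]] / h
  out
}

grad3 <- function(x, voxelSize) {
  list(gradAxis(x, 1, voxelSize[1]),
       gradAxis(x, 2, voxelSize[2]),
       gradAxis(x, 3, voxelSize[3]))
}

div3Adjoint <- function(g, voxelSize) {
  gradAxisAdjoint(g[[1]], 1, voxelSize[1]) +
    gradAxisAdjoint(g[[2]], 2, voxelSize[2]) +
    gradAxisAdjoint(g[[3]], 3, voxelSize[3])
}

#' Morphological edge mask from the signal magnitude
#'
#' Per finite-difference direction, voxels whose absolute magnitude gradient
#' exceeds the (1 - fraction) quantile within the ROI are flagged as edges
#' (mask value 0: the gradient-sparsity penalty is disabled there so vessels
#' and other sharp features survive regularisation); all other voxels get 1.
#' A constant magnitude has no edges and yields an all-ones mask.
#'
#' @param magnitude 3D magnitude array.
#' @param roi binary/logical ROI.
#' @param maskFraction fraction of ROI voxels to flag per direction
#'   (default 0.30, the top-30% magnitude gradients).
#' @return List of three binary arrays, one per gradient direction.
#' @export
edgeMask <- function(magnitude, roi, maskFraction = 0.30) {
  stopifnot3d(magnitude)
  roi <- roi > 0
  lapply(1:3, function(ax) {
    g <- abs(gradAxis(magnitude, ax, 1))
    thr <- stats::quantile(g[roi], 1 - maskFraction, names = FALSE, type = 7)
    m <- array(1, dim(magnitude))
    m[roi & g > thr] <- 0
    m
  })
}

#' Scale-specific phase-reliability mask
#'
#' Scale 1 is fully trusted (all ones). For scale l >= 2, the voxels of the
#' ROI whose phase second difference exceeds the
#' (100 - q * r_l / r_2)-th percentile within the ROI are zeroed, removing
#' their contribution from the data-fidelity term. With the defaults (q = 10,
#' radii 2/4/8/16 mm) the masked extents at scales 2-4 are 10, 20 and 40%.
#'
#' @param secondDiff second-difference map from [secondDifferenceMap()].
#' @param roi binary/logical ROI.
#' @param scaleIndex 1-based pyramid level.
#' @param qPercent base masking percentile q (default 10).
#' @param radiiMm full ascending radius schedule (needed for r_l / r_2).
#' @return Binary 3D array.
#' @export
reliabilityMask <- function(secondDiff, roi, scaleIndex, qPercent = 10,
                            radiiMm = c(2, 4, 8, 16)) {
  stopifnot3d(secondDiff)
  if (scaleIndex < 1) stop("scaleIndex must be >= 1")
  m <- array(1, dim(secondDiff))
  if (scaleIndex == 1L || qPercent == 0) return(m)
  if (length(radiiMm) < 2 || is.unsorted(radiiMm, strictly = TRUE))
    stop("radiiMm must be an ascending schedule with at least two scales")
  p <- qPercent * radiiMm[scaleIndex] / radiiMm[2]
  if (p > 100)
    stop("effective masking percentile exceeds 100%: mask would be empty")
  roi <- roi > 0
  thr <- stats::quantile(secondDiff[roi], 1 - p / 100, names = FALSE,
                         type = 7)
  m[roi & secondDiff > thr] <- 0
  m
}

#' MERIT residual reweighting
#'
#' Model-error reduction through iterative tuning: wherever the normalised
#' consistency residual exceeds the threshold f, the fidelity weight is
#' downscaled by the squared residual (`W = a' / rhat^2`); elsewhere the
#' pristine weight `a'` is kept. Recomputed from `a'` at every outer
#' iteration, so down-weighting never compounds.
#'
#' @param baseWeight pristine weight array a' (from [noiseWeight()]).
#' @param residual normalised residual array (ROI mean 1).
#' @param f threshold (default 6).
#' @return Reweighted array, elementwise <= `baseWeight`.
#' @export
meritReweight <- function(baseWeight, residual, f = 6) {
  stopifnot3d(baseWeight)
  w <- baseWeight
  idx <- residual > f
  w[idx] <- baseWeight[idx] / residual[idx]^2
  w
}

# Conjugate gradient for a symmetric positive semidefinite operator.
cgSolve <- function(applyA, b, tol, maxIter) {
  x <- array(0, dim(b))
  r <- b
  p <- r
  rs <- sum(r * r)
  b2 <- sqrt(rs)
  if (b2 == 0) return(x)
  for (i in seq_len(maxIter)) {
    Ap <- applyA(p)
    pAp <- sum(p * Ap)
    if (pAp <= 0) break # null-space direction; rhs component exhausted
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rsNew <- sum(r * r)
    if (sqrt(rsNew) / b2 < tol) break
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  x
}

#' Solve one pyramid scale
#'
#' Minimises `lambda ||Q W (exp(i C X) - exp(i phi'))||^2 + ||M grad X||_1`
#' where `C` is the chi-to-phase scaled, high-pass band-limited dipole
#' operator of this scale. Outer quasi-Newton iterations linearise the
#' complex exponential, reweight the L1 term with `1/sqrt(|grad X|^2 + e)`,
#' and solve the Gauss-Newton normal equations by CG to relative tolerance
#' `cgTol`; MERIT reweighting is applied between iterations and the loop
#' stops when the relative update norm drops below `outerTol`.
#'
#' @param phiHp high-pass filtered phase for this scale (3D array, rad, or a
#'   [FieldVolume-class]).
#' @param weights pristine noise weights a' (from [noiseWeight()]).
#' @param qmask binary reliability mask (from [reliabilityMask()]).
#' @param emask edge mask list (from [edgeMask()]) or NULL for no prior.
#' @param kernels a [KernelSet-class].
#' @param scaleIndex which SMV complement band-limits the forward model.
#' @param spec a [ScaleSpec-class].
#' @return A [ScaleResult-class] with `chiCum` left equal to `chiDelta`
#'   (accumulation happens in [runMSDI()]).
#' @export
solveScale <- function(phiHp, weights, qmask, emask, kernels, scaleIndex,
                       spec) {
  if (is(phiHp, "FieldVolume")) phiHp <- phiHp@values
  stopifnot3d(phiHp)
  if (!sameDim(phiHp, weights) || !sameDim(phiHp, qmask))
    stop("phiHp, weights and qmask must share one grid")
  grid <- kernels@grid
  if (!identical(dim(phiHp), as.integer(grid@shape)))
    stop("grid mismatch between inputs and kernels")
  vox <- grid@voxelSize
  op <- smvComplement(kernels, scaleIndex) * kernels@dipole *
    kernels@chiToPhase
  C <- function(x) reifftn(op * fftn(x))
  Ct <- function(x) reifftn(Conj(op) * fftn(x))
  m <- if (is.null(emask)) NULL else emask
  applyM <- function(g) {
    if (is.null(m)) g else list(m[[1]] * g[[1]], m[[2]] * g[[2]],
                                m[[3]] * g[[3]])
  }
  lambda <- spec@lambda
  expPhi <- exp(1i * phiHp)
  aprime <- weights
  W <- aprime
  X <- array(0, dim(phiHp))
  roiW <- qmask * aprime > 0
  cost <- matrix(numeric(0), ncol = 2,
                 dimnames = list(NULL, c("fidelity", "regulariser")))
  converged <- FALSE
  for (outer in seq_len(spec@maxOuter)) {
    qw <- qmask * W
    cx <- C(X)
    sinRes <- sin(cx - phiHp)
    # costs at current iterate
    fid <- sum((qw * Mod(exp(1i * cx) - expPhi))^2)
    gX <- applyM(grad3(X, vox))
    # anisotropic L1: per-component weak-derivative reweighting, as in the
    # quasi-Newton fixed-point solver family this scheme follows
    reg <- sum(abs(gX[[1]])) + sum(abs(gX[[2]])) + sum(abs(gX[[3]]))
    if (!is.finite(fid) || !is.finite(reg))
      stop(sprintf("non-finite cost at scale %d, outer iteration %d",
                   scaleIndex, outer))
    cost <- rbind(cost, c(fid, reg))
    vr <- lapply(gX, function(g) 1 / sqrt(g^2 + spec@epsilon))
    regGrad <- div3Adjoint(applyM(list(vr[[1]] * gX[[1]], vr[[2]] * gX[[2]],
                                       vr[[3]] * gX[[3]])), vox)
    rhs <- -(regGrad + 2 * lambda * Ct(qw^2 * sinRes))
    w2 <- qw^2
    applyA <- function(dx) {
      g <- applyM(grad3(dx, vox))
      div3Adjoint(applyM(list(vr[[1]] * g[[1]], vr[[2]] * g[[2]],
                              vr[[3]] * g[[3]])), vox) +
        2 * lambda * Ct(w2 * C(dx))
    }
    dx <- cgSolve(applyA, rhs, tol = spec@cgTol, maxIter = spec@maxCg)
    # backtracking on the current-weight objective guards the quasi-Newton
    # step against overshoot of the linearisation
    objAt <- function(Xt) {
      g <- applyM(grad3(Xt, vox))
      lambda * sum((qw * Mod(exp(1i * C(Xt)) - expPhi))^2) +
        sum(abs(g[[1]])) + sum(abs(g[[2]])) + sum(abs(g[[3]]))
    }
    obj0 <- lambda * fid + reg
    step <- 1
    repeat {
      if (objAt(X + step * dx) <= obj0 || step < 0.1) break
      step <- step / 2
    }
    dx <- step * dx
    X <- X + dx
    relStep <- sqrt(sum(dx^2)) / max(sqrt(sum(X^2)), .Machine$double.eps)
    # MERIT: normalised consistency residual of the current model fit,
    # measured with the pristine weights a' (Eq. 4 defines W from the
    # residual, so the residual itself cannot depend on W)
    res <- Mod(exp(1i * C(X)) - expPhi) * qmask * aprime
    mres <- mean(res[roiW])
    if (is.finite(mres) && mres > 0) {
      rhat <- res / mres
      W <- meritReweight(aprime, rhat, spec@meritF)
    }
    if (relStep < spec@outerTol) {
      converged <- TRUE
      break
    }
  }
  new("ScaleResult", scaleIndex = as.integer(scaleIndex), rMm = spec@rMm,
      chiDelta = X, chiCum = X, weightsFinal = W, qmask = qmask,
      costHistory = cost, converged = converged)
}
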