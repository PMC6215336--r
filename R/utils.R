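# Internal array/FFT helpers shared by all modules. All convolutions in the
# package are circular (FFT-based); kernels are built centred on the origin
# voxel with wrap-around so transfer functions carry zero phase.

fftn <- function(x) stats::fft(x)

ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Real part of the inverse FFT, for products known to be real signals.
reifftn <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

# DFT sample frequencies in cycles/mm (numpy fftfreq convention).
fftFreq <- function(n, d = 1) {
  k <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  k / (n * d)
}

# Signed spatial coordinate (mm) of each voxel relative to the origin voxel,
# with wrap-around: 0, 1, ..., then negative offsets. Used to rasterise
# origin-centred kernels.
wrapCoord <- function(n, d = 1) {
  x <- 0:(n - 1)
  x[x > n / 2] <- x[x > n / 2] - n
  x * d
}

# Expand three axis vectors into full 3D arrays (column-major broadcast).
axisArrays <- function(ax, ay, az) {
  nx <- length(ax); ny <- length(ay); nz <- length(az)
  list(
    x = array(rep(ax, times = ny * nz), dim = c(nx, ny, nz)),
    y = array(rep(rep(ay, each = nx), times = nz), dim = c(nx, ny, nz)),
    z = array(rep(az, each = nx * ny), dim = c(nx, ny, nz))
  )
}

# Shift an array by `by` voxels along `axis`, padding with `fill`.
arrShift <- function(x, axis, by, fill = NA_real_) {
  if (by == 0) return(x)
  d <- dim(x)
  n <- d[axis]
  if (abs(by) >= n) return(array(fill, dim = d))
  idx <- lapply(d, seq_len)
  src <- idx
  dst <- idx
  if (by > 0) {
    dst[[axis]] <- (by + 1):n
    src[[axis]] <- 1:(n - by)
  } else {
    dst[[axis]] <- 1:(n + by)
    src[[axis]] <- (1 - by):n
  }
  out <- array(fill, dim = d)
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

# Shift by an integer offset vector (dx, dy, dz).
arrShift3 <- function(x, off, fill = NA_real_) {
  for (ax in 1:3) if (off[ax] != 0) x <- arrShift(x, ax, off[ax], fill = fill)
  x
}

# Circular convolution with a kernel given by its transfer function.
convHat <- function(vol, hat) {
  reifftn(hat * fftn(vol))
}

stopifnot3d <- function(x, name = deparse(substitute(x))) {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3D array", name), call. = FALSE)
  invisible(x)
}

sameDim <- function(a, b) identical(dim(a), dim(b))

# Run an expression with a locally seeded RNG, restoring the global state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
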