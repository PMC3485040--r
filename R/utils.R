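# Internal numerical helpers shared across modules.

# Voxel-center coordinate grid (0-based indices) as a 3 x N matrix.
.voxelGrid <- function(dims) {
  g <- expand.grid(x = seq_len(dims[1]) - 1L, y = seq_len(dims[2]) - 1L,
                   z = seq_len(dims[3]) - 1L)
  t(as.matrix(g))
}

# Trilinear interpolation of a 3D array at (possibly fractional) 0-based
# voxel coordinates given as a 3 x N matrix. Out-of-field samples -> fill.
.trilinear <- function(vol, coords, fill = 0) {
  d <- dim(vol)
  x <- coords[1L, ]; y <- coords[2L, ]; z <- coords[3L, ]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  inside <- x0 >= 0 & y0 >= 0 & z0 >= 0 &
    x0 <= d[1] - 1 & y0 <= d[2] - 1 & z0 <= d[3] - 1 &
    (x0 + (fx > 0)) <= d[1] - 1 & (y0 + (fy > 0)) <= d[2] - 1 &
    (z0 + (fz > 0)) <= d[3] - 1
  out <- rep(fill, length(x))
  if (!any(inside)) return(out)
  x0i <- x0[inside]; y0i <- y0[inside]; z0i <- z0[inside]
  fxi <- fx[inside]; fyi <- fy[inside]; fzi <- fz[inside]
  x1i <- pmin(x0i + 1, d[1] - 1); y1i <- pmin(y0i + 1, d[2] - 1)
  z1i <- pmin(z0i + 1, d[3] - 1)
  idx <- function(i, j, k) 1 + i + d[1] * (j + d[2] * k)
  v000 <- vol[idx(x0i, y0i, z0i)]; v100 <- vol[idx(x1i, y0i, z0i)]
  v010 <- vol[idx(x0i, y1i, z0i)]; v110 <- vol[idx(x1i, y1i, z0i)]
  v001 <- vol[idx(x0i, y0i, z1i)]; v101 <- vol[idx(x1i, y0i, z1i)]
  v011 <- vol[idx(x0i, y1i, z1i)]; v111 <- vol[idx(x1i, y1i, z1i)]
  c00 <- v000 * (1 - fxi) + v100 * fxi
  c10 <- v010 * (1 - fxi) + v110 * fxi
  c01 <- v001 * (1 - fxi) + v101 * fxi
  c11 <- v011 * (1 - fxi) + v111 * fxi
  c0 <- c00 * (1 - fyi) + c10 * fyi
  c1 <- c01 * (1 - fyi) + c11 * fyi
  out[inside] <- c0 * (1 - fzi) + c1 * fzi
  out
}

# Block-average downsample of a 3D array by integer factor f per axis,
# with the voxel-to-world affine adjusted so voxel centers stay aligned:
# new voxel j covers old voxels f*j .. f*j+f-1, center at f*j + (f-1)/2.
.downsample3D <- function(vol, affine, factor) {
  if (factor == 1L) return(list(voxels = vol, affine = affine))
  d <- dim(vol)
  nd <- pmax(1L, d %/% factor)
  cropped <- vol[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                 seq_len(nd[3] * factor), drop = FALSE]
  a <- array(cropped, c(factor, nd[1], factor, nd[2], factor, nd[3]))
  out <- apply(a, c(2L, 4L, 6L), mean)
  shift <- diag(4)
  shift[1:3, 1:3] <- diag(3) * factor
  shift[1:3, 4] <- (factor - 1) / 2
  list(voxels = out, affine = affine %*% shift)
}

# Row-normalized truncated Gaussian convolution matrix for one axis.
# sigma in voxels; truncation at 6 sigma keeps the discrete kernel within
# ~1e-9 of the untruncated normalization.
.gaussMatrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- min(n - 1L, ceiling(6 * sigma))
  offs <- -r:r
  w <- exp(-offs^2 / (2 * sigma^2))
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    K[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  K
}

# Apply a matrix along one axis of a 3D array: out[i,,] = sum_j M[i,j] a[j,,].
.applyAlongAxis <- function(a, M, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = d[axis])
  res <- M %*% m
  out <- array(res, d[perm])
  aperm(out, order(perm))
}

# Separable Gaussian smoothing of a 3D array; sigmaVox per axis (voxels).
.smooth3D <- function(vol, sigmaVox) {
  d <- dim(vol)
  for (ax in 1:3) {
    if (sigmaVox[ax] > 0)
      vol <- .applyAlongAxis(vol, .gaussMatrix(d[ax], sigmaVox[ax]), ax)
  }
  vol
}

# Logical mask of voxels whose centers (world mm) satisfy the ellipsoid
# inequality sum(((x - c) / semi)^2) <= 1.
.ellipsoidMask <- function(dims, affine, center, semiAxes) {
  grid <- .voxelGrid(dims)
  world <- affine[1:3, 1:3] %*% grid + affine[1:3, 4]
  q <- ((world[1L, ] - center[1]) / semiAxes[1])^2 +
       ((world[2L, ] - center[2]) / semiAxes[2])^2 +
       ((world[3L, ] - center[3]) / semiAxes[3])^2
  array(q <= 1, dims)
}

.stopIf <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
}
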