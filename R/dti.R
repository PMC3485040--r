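# Diffusion tensor metrics: log-linear tensor estimation, eigenvalue
# maps, fractional anisotropy and mean diffusivity, ROI summaries.

#' DTI design matrix
#'
#' One row per volume of the log-linearized single-tensor model
#' ln S = ln S0 - b g' D g:
#' (-b gx^2, -b gy^2, -b gz^2, -2 b gx gy, -2 b gx gz, -2 b gy gz, 1),
#' mapping (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz, ln S0) to ln S. Requires at
#' least 6 unique nonzero directions plus a b = 0 volume for full rank.
#'
#' @param scheme a [DiffusionScheme].
#' @return n x 7 numeric matrix.
#' @export
buildDesignMatrix <- function(scheme) {
  stopifnot(is(scheme, "DiffusionScheme"))
  b <- bValues(scheme)
  g <- bVectors(scheme)
  dirs <- unique(round(t(g[, b > 0, drop = FALSE]), 6))
  .stopIf(nrow(dirs) < 6L,
          "need >= 6 unique nonzero gradient directions, got %d",
          nrow(dirs))
  X <- cbind(-b * g[1, ]^2, -b * g[2, ]^2, -b * g[3, ]^2,
             -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
             -2 * b * g[2, ] * g[3, ], 1)
  .stopIf(qr(X)$rank < 7L, "rank-deficient gradient scheme")
  unname(X)
}

#' Fit the diffusion tensor per voxel
#'
#' Ordinary least squares on log-signals for every voxel inside the
#' mask. Signals are clamped to a small positive floor (1e-6 of the
#' voxel's b = 0 mean) before the log. The symmetric tensor is
#' eigendecomposed per voxel; negative eigenvalues are clamped to 0 and
#' flagged. Voxels with an all-zero signal are flagged degenerate and
#' excluded from ROI summaries.
#'
#' @param dwi the diffusion-weighted [MriImage4D].
#' @param scheme the matching [DiffusionScheme].
#' @param mask a [LabelMap] (nonzero = analyze) or logical array.
#' @return A [TensorField-class].
#' @export
fitTensor <- function(dwi, scheme, mask) {
  stopifnot(is(dwi, "MriImage4D"))
  f <- .flatten4D(voxels(dwi))
  .stopIf(f$dims[4] != length(bValues(scheme)),
          "DWI volumes (%d) do not match the scheme (%d)",
          f$dims[4], length(bValues(scheme)))
  maskArr <- if (is(mask, "LabelMap")) labelArray(mask) != 0L
             else as.array(mask)
  .stopIf(!any(maskArr), "empty analysis mask")
  X <- buildDesignMatrix(scheme)
  Xinv <- solve(crossprod(X), t(X))     # 7 x n pseudoinverse
  dims <- f$dims[1:3]
  sel <- which(as.vector(maskArr))
  S <- f$mat[sel, , drop = FALSE]
  degenerate <- rowSums(S != 0) == 0L
  s0est <- rowMeans(S[, bValues(scheme) == 0, drop = FALSE])
  floorv <- pmax(1e-6 * s0est, .Machine$double.xmin)
  Sc <- pmax(S, floorv)                 # recycles per column
  beta <- t(Xinv %*% t(log(Sc)))        # nvox x 7
  coeffs <- array(0, c(dims, 6L))
  logS0 <- array(NA_real_, dims)
  evals <- array(NA_real_, c(dims, 3L))
  clamped <- array(FALSE, dims)
  degArr <- array(FALSE, dims)
  degArr[sel] <- degenerate
  cf <- matrix(coeffs, prod(dims), 6L)
  cf[sel, ] <- beta[, 1:6]
  coeffs <- array(cf, c(dims, 6L))
  logS0[sel] <- beta[, 7L]
  ev <- matrix(NA_real_, length(sel), 3L)
  cl <- logical(length(sel))
  for (i in seq_along(sel)) {
    if (degenerate[i]) next
    D <- matrix(c(beta[i, 1], beta[i, 4], beta[i, 5],
                  beta[i, 4], beta[i, 2], beta[i, 6],
                  beta[i, 5], beta[i, 6], beta[i, 3]), 3L, 3L)
    lam <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    if (any(lam < 0)) { cl[i] <- TRUE; lam <- pmax(lam, 0) }
    ev[i, ] <- sort(lam, decreasing = TRUE)
  }
  evm <- matrix(evals, prod(dims), 3L)
  evm[sel, ] <- ev
  evals <- array(evm, c(dims, 3L))
  clamped[sel] <- cl
  new("TensorField", coeffs = coeffs, logS0 = logS0, mask = maskArr,
      evals = evals, clamped = clamped, degenerate = degArr,
      voxelDims = voxelDims(dwi))
}

#' Fractional anisotropy from eigenvalues
#'
#' FA = sqrt(3/2) sqrt(sum_i (li - lbar)^2) / sqrt(sum_i li^2): the
#' normalized dispersion of the three tensor eigenvalues, 0 for
#' isotropic diffusion, 1 for purely one-dimensional diffusion.
#' Vectorized over voxels; an all-zero triple is undefined and returns
#' NA.
#'
#' @param l1,l2,l3 eigenvalue vectors (mm^2/s).
#' @return FA values in [0, 1] (NA where undefined).
#' @examples
#' fa(1, 1, 1)  # 0
#' fa(1, 0, 0)  # 1
#' @export
fa <- function(l1, l2, l3) {
  lbar <- (l1 + l2 + l3) / 3
  num <- (l1 - lbar)^2 + (l2 - lbar)^2 + (l3 - lbar)^2
  den <- l1^2 + l2^2 + l3^2
  out <- sqrt(1.5) * sqrt(num / den)
  out[den == 0] <- NA_real_
  pmin(pmax(out, 0), 1)
}

#' Mean diffusivity from eigenvalues
#'
#' MD = (l1 + l2 + l3) / 3, the arithmetic mean of the eigenvalues
#' (equivalently trace(D) / 3), in mm^2/s.
#'
#' @param l1,l2,l3 eigenvalue vectors (mm^2/s).
#' @return MD values.
#' @export
md <- function(l1, l2, l3) (l1 + l2 + l3) / 3

.tensorEigen <- function(tensorField) {
  ev <- matrix(tensorField@evals, ncol = 3L)
  good <- as.vector(tensorField@mask) & !as.vector(tensorField@degenerate)
  list(ev = ev, good = good)
}

#' FA / MD scalar maps from a tensor field
#'
#' @param tensorField a [TensorField-class].
#' @return A [ScalarMap-class].
#' @export
faMap <- function(tensorField) {
  e <- .tensorEigen(tensorField)
  v <- array(0, dim(tensorField@mask))
  v[e$good] <- fa(e$ev[e$good, 1], e$ev[e$good, 2], e$ev[e$good, 3])
  v[is.na(v)] <- 0
  new("ScalarMap", values = v,
      mask = array(e$good, dim(tensorField@mask)), metric = "FA",
      voxelDims = tensorField@voxelDims)
}

#' @rdname faMap
#' @export
mdMap <- function(tensorField) {
  e <- .tensorEigen(tensorField)
  v <- array(0, dim(tensorField@mask))
  v[e$good] <- md(e$ev[e$good, 1], e$ev[e$good, 2], e$ev[e$good, 3])
  new("ScalarMap", values = v,
      mask = array(e$good, dim(tensorField@mask)), metric = "MD",
      voxelDims = tensorField@voxelDims)
}

#' ROI summary of a scalar map
#'
#' Mean and sample standard deviation of a scalar map over the
#' intersection of an ROI with the map's analysis mask. A single-voxel
#' ROI has undefined sd, reported as 0 with `sdDefined = FALSE`.
#'
#' @param scalarMap a [ScalarMap-class].
#' @param roiMask a [LabelMap] (nonzero = ROI) or logical array.
#' @return A list with `mean`, `sd`, `n`, `sdDefined`.
#' @export
roiMeanMetric <- function(scalarMap, roiMask) {
  stopifnot(is(scalarMap, "ScalarMap"))
  roi <- if (is(roiMask, "LabelMap")) labelArray(roiMask) != 0L
         else as.array(roiMask)
  sel <- roi & scalarMap@mask
  .stopIf(!any(sel), "ROI does not intersect the analysis mask")
  v <- scalarMap@values[sel]
  if (length(v) == 1L)
    return(list(mean = v, sd = 0, n = 1L, sdDefined = FALSE))
  list(mean = mean(v), sd = stats::sd(v), n = length(v), sdDefined = TRUE)
}
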