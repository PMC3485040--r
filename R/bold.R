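# BOLD preprocessing chain and temporal-SNR metric: discard dummy
# volumes, brain mask, spatial smoothing, high-pass (DCT) filtering,
# nuisance regression, ROI tSNR, and the motion-trace summary.

# 4D voxels as a (voxel x time) matrix and back.
.flatten4D <- function(vox) {
  d <- dim(vox)
  list(mat = matrix(vox, prod(d[1:3]), d[4]), dims = d)
}

#' Discard initial volumes
#'
#' Drops the first `n` volumes of a 4D series (dummy scans acquired
#' before longitudinal magnetization reaches steady state).
#'
#' @param img4d an [MriImage4D].
#' @param n number of initial volumes to discard (default 4).
#' @return An [MriImage4D] with `n` fewer volumes.
#' @export
discardInitialVolumes <- function(img4d, n = 4L) {
  stopifnot(is(img4d, "MriImage4D"))
  nt <- dim(voxels(img4d))[4]
  .stopIf(n >= nt, "cannot discard %d of %d volumes", n, nt)
  if (n == 0L) return(img4d)
  v <- voxels(img4d)[, , , (n + 1L):nt, drop = FALSE]
  mriImage4D(v, voxelDims = voxelDims(img4d), tr = repetitionTime(img4d),
             affine = imageAffine(img4d))
}

#' Threshold-based brain mask
#'
#' A simple skull-stripping stand-in: voxels above a fraction of the
#' robust intensity range (2nd-98th percentile) are kept, and only the
#' largest 6-connected component survives.
#'
#' @param image an [MriImage3D], or an [MriImage4D] whose temporal mean
#'   is used.
#' @param fraction threshold as a fraction of the robust range.
#' @return A [LabelMap] with label 1 = brain.
#' @export
makeBrainMask <- function(image, fraction = 0.25) {
  if (is(image, "MriImage4D")) {
    f <- .flatten4D(voxels(image))
    vol <- array(rowMeans(f$mat), f$dims[1:3])
    vd <- voxelDims(image); aff <- imageAffine(image)
  } else {
    stopifnot(is(image, "MriImage3D"))
    vol <- voxels(image); vd <- voxelDims(image)
    aff <- imageAffine(image)
  }
  q <- stats::quantile(vol, c(0.02, 0.98), names = FALSE)
  .stopIf(q[2] <= q[1], "constant image; cannot threshold")
  thr <- q[1] + fraction * (q[2] - q[1])
  mask <- vol > thr
  mask <- .largestComponent(mask)
  labelMap(array(as.integer(mask), dim(vol)),
           regionNames = c("1" = "brain"), voxelDims = vd, affine = aff)
}

# Largest 6-connected component of a logical 3D array (igraph on the
# voxel adjacency graph).
.largestComponent <- function(mask) {
  idx <- which(mask)
  if (length(idx) <= 1L) return(mask)
  d <- dim(mask)
  co <- arrayInd(idx, d)
  id <- integer(prod(d)); id[idx] <- seq_along(idx)
  edges <- integer(0)
  for (ax in 1:3) {
    nb <- co; nb[, ax] <- nb[, ax] + 1L
    ok <- nb[, ax] <= d[ax]
    lin <- (nb[ok, 1] - 1L) + d[1] * ((nb[ok, 2] - 1L) +
                                        d[2] * (nb[ok, 3] - 1L)) + 1L
    hit <- id[lin] > 0L
    edges <- c(edges, rbind(which(ok)[hit], id[lin[hit]]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)
  keep <- idx[comp$membership == which.max(comp$csize)]
  out <- array(FALSE, d)
  out[keep] <- TRUE
  out
}

#' Spatial Gaussian smoothing
#'
#' Convolves each volume with a separable Gaussian of the given
#' full-width at half-maximum (mm), per-axis sigma =
#' FWHM / (2 sqrt(2 ln 2)) scaled by the voxel dimensions. The kernel is
#' renormalized at the lattice edges so constant images are preserved;
#' `fwhm = 0` is the identity.
#'
#' @param img an [MriImage4D] or [MriImage3D].
#' @param fwhm full-width at half-maximum (mm), >= 0.
#' @return The smoothed image, same class as the input.
#' @export
smoothGaussian <- function(img, fwhm = 5) {
  .stopIf(fwhm < 0, "fwhm must be >= 0")
  if (fwhm == 0) return(img)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  sigVox <- sigma / voxelDims(img)
  if (is(img, "MriImage3D")) {
    return(mriImage3D(.smooth3D(voxels(img), sigVox),
                      voxelDims = voxelDims(img),
                      affine = imageAffine(img)))
  }
  stopifnot(is(img, "MriImage4D"))
  v <- voxels(img)
  for (t in seq_len(dim(v)[4]))
    v[, , , t] <- .smooth3D(v[, , , t], sigVox)
  mriImage4D(v, voxelDims = voxelDims(img), tr = repetitionTime(img),
             affine = imageAffine(img))
}

# Harmonic drift basis: sine and cosine pairs at k = 1 .. K whole
# cycles over the acquisition window, K chosen so every retained period
# is >= the cutoff. Full-cycle harmonics sum to zero over the window, so
# removing their projection preserves the temporal mean exactly, and a
# slow drift of any phase at a retained frequency is removed completely.
.driftBasis <- function(nt, tr, cutoffS) {
  K <- floor(nt * tr / cutoffS)
  if (K < 1L) return(NULL)
  tt <- seq_len(nt) - 1
  do.call(cbind, lapply(seq_len(K), function(k)
    cbind(sin(2 * pi * k * tt / nt), cos(2 * pi * k * tt / nt))))
}

#' Temporal high-pass filtering
#'
#' Removes slow drifts by regressing out a harmonic (sine/cosine) basis
#' of all whole-cycle periods at or above the cutoff; the constant term
#' is retained, so the temporal mean of every voxel is preserved.
#'
#' @param img4d an [MriImage4D].
#' @param cutoffS high-pass cutoff period (s); must exceed 2 TR.
#' @return The filtered [MriImage4D].
#' @export
highpassTemporal <- function(img4d, cutoffS = 150) {
  stopifnot(is(img4d, "MriImage4D"))
  tr <- repetitionTime(img4d)
  .stopIf(cutoffS <= 2 * tr, "cutoff (%g s) must exceed 2 TR (%g s)",
          cutoffS, 2 * tr)
  f <- .flatten4D(voxels(img4d))
  B <- .driftBasis(f$dims[4], tr, cutoffS)
  if (is.null(B)) return(img4d)
  # project out the drift basis: Y - B (B'B)^-1 B' Y, applied row-wise
  coef <- solve(crossprod(B), crossprod(B, t(f$mat)))
  res <- f$mat - t(B %*% coef)
  mriImage4D(array(res, f$dims), voxelDims = voxelDims(img4d), tr = tr,
             affine = imageAffine(img4d))
}

#' Nuisance regression
#'
#' Regresses a set of nuisance time series (motion parameters, white
#' matter / CSF / global means) out of every voxel by ordinary least
#' squares, then reinstates the voxel's temporal mean so downstream
#' tSNR remains defined.
#'
#' @param img4d an [MriImage4D].
#' @param regressors t x p numeric matrix, one column per nuisance
#'   series; an intercept is added internally.
#' @return The residual [MriImage4D] (plus temporal means).
#' @export
nuisanceRegress <- function(img4d, regressors) {
  stopifnot(is(img4d, "MriImage4D"))
  f <- .flatten4D(voxels(img4d))
  X <- cbind(1, as.matrix(regressors))
  .stopIf(nrow(X) != f$dims[4],
          "regressor rows (%d) do not match the time dimension (%d)",
          nrow(X), f$dims[4])
  .stopIf(qr(X)$rank < ncol(X), "rank-deficient nuisance design matrix")
  coef <- solve(crossprod(X), crossprod(X, t(f$mat)))
  fit <- t(X %*% coef)
  means <- rowMeans(f$mat)
  res <- f$mat - fit + means
  mriImage4D(array(res, f$dims), voxelDims = voxelDims(img4d),
             tr = repetitionTime(img4d), affine = imageAffine(img4d))
}

#' Motion and anatomical nuisance regressor assembly
#'
#' Convenience builder for the standard nuisance set: the six rigid
#' motion parameters plus the mean time course of any supplied masks
#' (white matter, CSF, whole brain / global signal).
#'
#' @param img4d the [MriImage4D] the masks apply to.
#' @param motion an optional [MotionTrace] (must match the time
#'   dimension).
#' @param masks optional named list of [LabelMap]s or logical arrays.
#' @return A t x p numeric matrix of regressors.
#' @export
buildNuisanceRegressors <- function(img4d, motion = NULL, masks = list()) {
  f <- .flatten4D(voxels(img4d))
  out <- NULL
  if (!is.null(motion)) {
    p <- motionParams(motion)
    .stopIf(nrow(p) != f$dims[4],
            "motion trace length (%d) does not match volumes (%d)",
            nrow(p), f$dims[4])
    out <- p
  }
  for (nm in names(masks)) {
    m <- masks[[nm]]
    mask <- if (is(m, "LabelMap")) labelArray(m) != 0L else as.array(m)
    tc <- colMeans(f$mat[as.vector(mask), , drop = FALSE])
    out <- cbind(out, tc)
  }
  out
}

#' ROI temporal signal-to-noise ratio
#'
#' Averages all ROI voxels within each volume to form the ROI-mean time
#' course m(t), then reports tSNR = mean(m) / sd(m) (sample sd). ROI
#' aggregation before the ratio reflects that voxels of one functional
#' network share coherent spontaneous fluctuations; a voxelwise mode
#' (median over per-voxel tSNR) is available behind `voxelwise`.
#'
#' @param img4d a (preprocessed) [MriImage4D].
#' @param roiMask a [LabelMap] (nonzero = ROI) or logical array.
#' @param voxelwise if TRUE, report the median of per-voxel tSNR
#'   instead.
#' @return A [TsnrResult-class].
#' @export
roiTsnr <- function(img4d, roiMask, voxelwise = FALSE) {
  stopifnot(is(img4d, "MriImage4D"))
  mask <- if (is(roiMask, "LabelMap")) labelArray(roiMask) != 0L
          else as.array(roiMask)
  f <- .flatten4D(voxels(img4d))
  .stopIf(length(mask) != nrow(f$mat),
          "ROI mask dimensions do not match the image")
  .stopIf(!any(mask), "empty ROI mask")
  .stopIf(f$dims[4] < 8L, "need at least 8 timepoints, got %d", f$dims[4])
  sub <- f$mat[as.vector(mask), , drop = FALSE]
  if (voxelwise) {
    mus <- rowMeans(sub)
    sds <- apply(sub, 1L, stats::sd)
    .stopIf(all(sds == 0), "constant series; tSNR undefined")
    tsnr <- stats::median(mus[sds > 0] / sds[sds > 0])
    m <- colMeans(sub)
    return(new("TsnrResult", tsnr = tsnr, timecourse = m,
               temporalMean = mean(m), temporalSd = stats::sd(m),
               nVoxels = sum(mask), nTimepoints = f$dims[4]))
  }
  m <- colMeans(sub)
  sd_m <- stats::sd(m)
  .stopIf(sd_m == 0, "constant ROI-mean series; tSNR undefined")
  new("TsnrResult", tsnr = mean(m) / sd_m, timecourse = m,
      temporalMean = mean(m), temporalSd = sd_m,
      nVoxels = sum(mask), nTimepoints = f$dims[4])
}

#' Standard BOLD preprocessing chain
#'
#' Discard initial volumes, smooth spatially, high-pass filter, and
#' regress out nuisance series — the chain applied before tSNR.
#'
#' @param img4d an [MriImage4D].
#' @param discard initial volumes to drop.
#' @param fwhm smoothing FWHM (mm).
#' @param highpass high-pass cutoff (s).
#' @param regressors optional t x p matrix (rows must match the series
#'   length after discarding).
#' @return The preprocessed [MriImage4D].
#' @export
preprocessBold <- function(img4d, discard = 4L, fwhm = 5, highpass = 150,
                           regressors = NULL) {
  out <- discardInitialVolumes(img4d, discard)
  out <- smoothGaussian(out, fwhm)
  out <- highpassTemporal(out, highpass)
  if (!is.null(regressors)) out <- nuisanceRegress(out, regressors)
  out
}

#' Maximum adjacent-volume displacement
#'
#' Largest Euclidean translation difference (mm) between consecutive
#' volumes of a motion trace. Rotations are not folded into the mm
#' figure (no head-radius convention is assumed); the maximum adjacent
#' rotation angle is reported separately.
#'
#' @param trace a [MotionTrace] with at least 2 volumes.
#' @return A list with `maxTranslation` (mm) and `maxRotation` (rad).
#' @export
maxAdjacentDisplacement <- function(trace) {
  stopifnot(is(trace, "MotionTrace"))
  p <- motionParams(trace)
  .stopIf(nrow(p) < 2L, "need at least 2 volumes to compare")
  dtr <- diff(p[, 4:6, drop = FALSE])
  drot <- diff(p[, 1:3, drop = FALSE])
  list(maxTranslation = max(sqrt(rowSums(dtr^2))),
       maxRotation = max(sqrt(rowSums(drot^2))))
}
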