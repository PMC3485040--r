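# Structural (T1) metrics: global intensity normalization, ROI
# volumetry, 12-parameter affine registration with stretch-factor
# decomposition, and the background-intensity motion screening ratio.

#' Global intensity normalization
#'
#' Rescales an image so that its mean intensity within the brain mask
#' equals a reference value: the image is multiplied by the scaling
#' factor G = referenceMean / S, where S is the whole-brain mean of the
#' input. Compensates session-to-session global intensity differences
#' (coil loading, receiver gain) before volumetry.
#'
#' @param image an [MriImage3D].
#' @param brainMask a [LabelMap] (nonzero = brain) or logical array of
#'   the same dimensions.
#' @param referenceMean target within-mask mean intensity.
#' @return A list with elements `image` (the rescaled [MriImage3D]) and
#'   `result` (a [NormalizationResult-class]).
#' @export
globalIntensityNormalize <- function(image, brainMask, referenceMean = 1000) {
  stopifnot(is(image, "MriImage3D"))
  mask <- if (is(brainMask, "LabelMap")) labelArray(brainMask) != 0L
          else as.array(brainMask)
  .stopIf(!all(dim(mask) == dim(voxels(image))),
          "mask dimensions do not match the image")
  .stopIf(!any(mask), "empty brain mask")
  s <- mean(voxels(image)[mask])
  .stopIf(!is.finite(s) || s <= 0,
          "whole-brain mean must be positive, got %g", s)
  g <- referenceMean / s
  out <- mriImage3D(voxels(image) * g, voxelDims = voxelDims(image),
                    affine = imageAffine(image))
  list(image = out,
       result = new("NormalizationResult", scale = g, inputMean = s,
                    referenceMean = referenceMean))
}

#' ROI volumes from a label map
#'
#' Volume of every named region: voxel count times voxel volume,
#' reported in cm^3. A named label absent from the lattice yields volume
#' 0 with a warning.
#'
#' @param labelmap a [LabelMap].
#' @param voxelDims optional length-3 voxel dimensions (mm) overriding
#'   the label map's own.
#' @return Named numeric vector of volumes (cm^3), one per region name.
#' @examples
#' lab <- labelMap(array(rep(c(0L, 1L), c(500, 500)), c(10, 10, 10)),
#'                 c("1" = "roi"))
#' roiVolumes(lab)  # 0.5 cm^3
#' @export
roiVolumes <- function(labelmap, voxelDims = NULL) {
  stopifnot(is(labelmap, "LabelMap"))
  vd <- if (is.null(voxelDims)) voxelDims(labelmap) else voxelDims
  .stopIf(any(vd <= 0), "voxel dimensions must be positive")
  vv <- prod(vd) / 1000  # mm^3 -> cm^3
  labs <- labelArray(labelmap)
  nm <- regionNames(labelmap)
  out <- numeric(length(nm))
  names(out) <- nm
  for (i in seq_along(nm)) {
    cnt <- sum(labs == as.integer(names(nm)[i]))
    if (cnt == 0L)
      warning("label ", names(nm)[i], " (", nm[i],
              ") absent from the label map; volume 0")
    out[i] <- cnt * vv
  }
  out
}

#' Registration options
#'
#' Settings for [registerAffine()]: pyramid subsampling levels, the
#' number of coordinate-descent sweeps and Nelder-Mead polish iterations
#' per level, and the initial search steps per parameter family.
#'
#' @param levels integer subsampling factors, coarse to fine.
#' @param sweeps coordinate-descent sweeps per level.
#' @param nmIter Nelder-Mead iteration cap per level.
#' @param stepTrans,stepRot,stepScale,stepSkew initial line-search steps
#'   (mm, rad, unitless, unitless).
#' @param tol minimum cost improvement over the identity required to
#'   accept a transform.
#' @return A list of options.
#' @export
registrationOptions <- function(levels = c(4L, 2L, 1L), sweeps = 3L,
                                nmIter = 300L, stepTrans = NULL,
                                stepRot = 0.02, stepScale = 0.02,
                                stepSkew = 0.02, tol = 1e-9) {
  list(levels = as.integer(levels), sweeps = as.integer(sweeps),
       nmIter = as.integer(nmIter), stepTrans = stepTrans,
       stepRot = stepRot, stepScale = stepScale, stepSkew = stepSkew,
       tol = tol)
}

# 12 parameters -> 4x4 affine: T . Rx Ry Rz . diag(s) . unit upper
# triangular skew, applied about a fixed center (decouples the
# translation parameters from rotation/scale, which helps convergence;
# the linear part, hence the stretch decomposition, is unaffected).
.paramsToAffine <- function(p, center = c(0, 0, 0)) {
  tr <- p[1:3]; r <- p[4:6]; s <- p[7:9]; k <- p[10:12]
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  K <- rbind(c(1, k[1], k[2]), c(0, 1, k[3]), c(0, 0, 1))
  L <- Rx %*% Ry %*% Rz %*% diag(s) %*% K
  A <- diag(4)
  A[1:3, 1:3] <- L
  A[1:3, 4] <- tr + center - L %*% center
  A
}

# Normalized-MSE registration cost: resample moving into the template
# grid through A, z-score both, mean squared difference.
.regCost <- function(p, movVox, movAffine, tmpVox, tmpAffine, grid,
                     center = c(0, 0, 0)) {
  A <- .paramsToAffine(p, center)
  M <- solve(movAffine) %*% solve(A) %*% tmpAffine
  src <- M %*% grid
  v <- .trilinear(movVox, src[1:3, , drop = FALSE])
  sv <- stats::sd(v); st <- stats::sd(tmpVox)
  if (sv == 0 || st == 0) return(1e6)
  mean(((v - mean(v)) / sv - (tmpVox - mean(tmpVox)) / st)^2)
}

#' 12-parameter affine registration
#'
#' Registers a moving 3D image to a template with a 12-parameter affine
#' (3 translations, 3 rotations, 3 scales, 3 skews), minimizing the mean
#' squared intensity difference after mean/variance normalization over a
#' multi-resolution pyramid (default 4, 2, 1 subsampling). Optimization
#' is a deterministic coordinate-wise line search followed by a
#' Nelder-Mead polish at each level. If the final cost does not improve
#' on the identity beyond `tol`, the identity is returned with
#' `converged = FALSE`.
#'
#' @param moving,template [MriImage3D] images with overlapping fields of
#'   view.
#' @param options a list from [registrationOptions()].
#' @return An [AffineTransform] mapping moving world coordinates to
#'   template world coordinates.
#' @seealso [decomposeScales()] for stretch factors,
#'   [applyAffineToImage()] to resample.
#' @export
registerAffine <- function(moving, template, options = registrationOptions()) {
  stopifnot(is(moving, "MriImage3D"), is(template, "MriImage3D"))
  p0 <- c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0)
  tdims <- dim(voxels(template))
  center <- as.vector(imageAffine(template) %*% c((tdims - 1) / 2, 1))[1:3]
  fullGrid <- rbind(.voxelGrid(tdims), 1)
  fullCost <- function(p) .regCost(p, voxels(moving), imageAffine(moving),
                                   as.vector(voxels(template)),
                                   imageAffine(template), fullGrid, center)
  cIdent <- fullCost(p0)
  if (cIdent < 1e-14) {  # already perfectly aligned
    return(affineTransform(diag(4), converged = TRUE))
  }
  p <- p0
  for (f in options$levels) {
    mv <- .downsample3D(voxels(moving), imageAffine(moving), f)
    tp <- .downsample3D(voxels(template), imageAffine(template), f)
    grid <- rbind(.voxelGrid(dim(tp$voxels)), 1)
    tmpVec <- as.vector(tp$voxels)
    cost <- function(p) .regCost(p, mv$voxels, mv$affine, tmpVec,
                                 tp$affine, grid, center)
    stepT <- if (is.null(options$stepTrans))
      max(voxelDims(template)) * f else options$stepTrans * f
    steps <- c(rep(stepT, 3), rep(options$stepRot, 3),
               rep(options$stepScale, 3), rep(options$stepSkew, 3))
    cur <- cost(p)
    for (sweep in seq_len(options$sweeps)) {
      for (i in seq_len(12L)) {
        d <- steps[i]
        while (d > steps[i] / 256) {
          repeat {  # greedy moves in the better direction at this step
            moved <- FALSE
            for (sgn in c(1, -1)) {
              cand <- p; cand[i] <- cand[i] + sgn * d
              cc <- cost(cand)
              if (cc < cur - 1e-15) {
                p <- cand; cur <- cc; moved <- TRUE; break
              }
            }
            if (!moved) break
          }
          d <- d / 2
        }
      }
    }
    opt <- stats::optim(p, cost, method = "Nelder-Mead",
                        control = list(maxit = options$nmIter,
                                       reltol = 1e-12,
                                       parscale = c(rep(stepT / 2, 3),
                                                    rep(0.005, 9))))
    if (opt$value < cur) { p <- opt$par; cur <- opt$value }
  }
  cFinal <- fullCost(p)
  if (cFinal >= cIdent - options$tol) {
    return(affineTransform(diag(4), converged = FALSE))
  }
  affineTransform(.paramsToAffine(p, center), converged = TRUE)
}

#' Decompose an affine into rotation, scales and skews
#'
#' Factors the linear part L of an affine transform as L = R S K with R
#' a rotation, S = diag(sx, sy, sz) positive per-axis stretch factors
#' and K a unit upper-triangular skew (the Gram-Schmidt / QR
#' factorization, as in FSL's avscale). The determinant of L — the
#' volumetric stretch, an Atlas-Scaling-Factor analogue — equals
#' sx sy sz and is reported alongside. A negative determinant
#' (reflection) is an error.
#'
#' @param transform an [AffineTransform] or 4x4 matrix.
#' @return A [ScaleDecomposition-class].
#' @examples
#' d <- decomposeScales(affineTransform(diag(c(1.1, 0.9, 1.2, 1))))
#' d@scales       # 1.1 0.9 1.2
#' d@determinant  # 1.188
#' @export
decomposeScales <- function(transform) {
  A <- if (is(transform, "AffineTransform")) transformMatrix(transform)
       else transform
  L <- A[1:3, 1:3]
  dt <- det(L)
  .stopIf(abs(dt) < 1e-12, "singular linear part")
  qrd <- qr(L)
  Q <- qr.Q(qrd); R <- qr.R(qrd)
  sgn <- sign(diag(R))
  Q <- Q %*% diag(sgn); R <- diag(sgn) %*% R
  if (dt < 0) {
    ax <- c("x", "y", "z")[which.min(diag(qr.R(qrd)) * sgn)]
    stop(sprintf(
      "negative determinant (%.6g): reflection detected (flipped %s axis)",
      dt, ax), call. = FALSE)
  }
  s <- diag(R)
  K <- diag(1 / s) %*% R
  new("ScaleDecomposition", scales = s,
      skews = c(K[1, 2], K[1, 3], K[2, 3]), rotation = Q, determinant = dt)
}

#' Background QC region bounds
#'
#' Closed 1-based voxel-index intervals for the two 8000-voxel
#' background regions of the T1 motion screening ratio: a region
#' anterior to the head (motion-sensitive, in the phase-encoding
#' direction) and a region superior to the eyes (reference). Defaults
#' are the regions used on a 256-matrix sagittal acquisition.
#'
#' @param anterior,superior 3x2 integer matrices of [lo, hi] per axis.
#' @return A [QcRoiBounds-class].
#' @export
qcRoiBounds <- function(anterior = rbind(x = c(90L, 109L),
                                         y = c(246L, 255L),
                                         z = c(186L, 225L)),
                        superior = rbind(x = c(65L, 84L),
                                         y = c(156L, 195L),
                                         z = c(246L, 255L))) {
  new("QcRoiBounds", anterior = anterior, superior = superior)
}

#' @rdname qcRoiBounds
#' @param bounds a [QcRoiBounds-class].
#' @export
qcRegionVoxelCounts <- function(bounds) {
  stopifnot(is(bounds, "QcRoiBounds"))
  c(anterior = as.integer(prod(bounds@anterior[, 2] -
                                 bounds@anterior[, 1] + 1L)),
    superior = as.integer(prod(bounds@superior[, 2] -
                                 bounds@superior[, 1] + 1L)))
}

.regionMean <- function(vox, b) {
  d <- dim(vox)
  .stopIf(any(b[, 1] < 1L) || any(b[, 2] > d),
          "QC region out of the image bounds")
  mean(vox[b[1, 1]:b[1, 2], b[2, 1]:b[2, 2], b[3, 1]:b[3, 2]])
}

#' T1 background motion ratio
#'
#' Ratio of mean background intensity in the anterior region (sensitive
#' to motion ghosting along the anterior-posterior phase-encoding
#' direction) over the superior region (reference). A ratio above 1
#' raises a motion concern and flags the scan for visual inspection.
#'
#' @param image an [MriImage3D].
#' @param bounds a [QcRoiBounds-class]; defaults to [qcRoiBounds()].
#' @return A list with `ratio`, `flag` (ratio > 1), `anteriorMean`,
#'   `superiorMean`.
#' @export
backgroundMotionRatio <- function(image, bounds = qcRoiBounds()) {
  stopifnot(is(image, "MriImage3D"))
  vox <- voxels(image)
  am <- .regionMean(vox, bounds@anterior)
  sm <- .regionMean(vox, bounds@superior)
  .stopIf(sm == 0, "superior region mean is zero; ratio undefined")
  ratio <- am / sm
  list(ratio = ratio, flag = ratio > 1, anteriorMean = am,
       superiorMean = sm)
}
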