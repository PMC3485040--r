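#' @import methods
NULL

.checkAffine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4L, 4L)))
    return("affine must be a 4x4 matrix")
  if (!all(is.finite(affine)))
    return("affine must be finite")
  if (max(abs(affine[4L, ] - c(0, 0, 0, 1))) > 1e-6)
    return("affine bottom row must be (0, 0, 0, 1)")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100)
    return("affine linear part is singular")
  NULL
}

#' 3D MRI volume
#'
#' A scalar 3D voxel lattice together with its voxel-to-world affine (mm)
#' and voxel dimensions (mm). Intensities are stored as doubles in
#' arbitrary units. The affine maps 0-based voxel indices to world mm.
#'
#' @slot voxels 3D numeric array of intensities.
#' @slot affine 4x4 homogeneous voxel-to-world matrix (mm).
#' @slot voxelDims length-3 numeric, voxel edge lengths (mm).
#' @exportClass MriImage3D
setClass("MriImage3D",
  representation(voxels = "array", affine = "matrix", voxelDims = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 3L)
      return("voxels must be a 3D array")
    if (any(dim(object@voxels) < 1L))
      return("each lattice dimension must be >= 1")
    if (length(object@voxelDims) != 3L || any(!is.finite(object@voxelDims)) ||
        any(object@voxelDims <= 0))
      return("voxelDims must be 3 positive finite values")
    msg <- .checkAffine(object@affine)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' 4D MRI series
#'
#' A 4D (x, y, z, t) voxel lattice with voxel-to-world affine, voxel
#' dimensions and repetition time. Used for BOLD and diffusion-weighted
#' series.
#'
#' @slot voxels 4D numeric array.
#' @slot affine 4x4 homogeneous voxel-to-world matrix (mm).
#' @slot voxelDims length-3 numeric (mm).
#' @slot tr repetition time (s).
#' @exportClass MriImage4D
setClass("MriImage4D",
  representation(voxels = "array", affine = "matrix", voxelDims = "numeric",
                 tr = "numeric"),
  validity = function(object) {
    if (length(dim(object@voxels)) != 4L)
      return("voxels must be a 4D array")
    if (dim(object@voxels)[4L] < 2L)
      return("time dimension must be >= 2")
    if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
      return("voxelDims must be 3 positive values")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
      return("tr must be a single positive value (seconds)")
    msg <- .checkAffine(object@affine)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' Integer label map
#'
#' A 3D integer lattice of region labels plus a label -> region-name
#' table. Label 0 is reserved for background and never named.
#'
#' @slot labels 3D integer array.
#' @slot regionNames named character vector; names are label integers as
#'   strings, values are region names.
#' @slot affine 4x4 voxel-to-world matrix (mm).
#' @slot voxelDims length-3 numeric (mm).
#' @exportClass LabelMap
setClass("LabelMap",
  representation(labels = "array", regionNames = "character",
                 affine = "matrix", voxelDims = "numeric"),
  validity = function(object) {
    if (length(dim(object@labels)) != 3L)
      return("labels must be a 3D array")
    if (!is.integer(object@labels))
      return("labels must be integer")
    present <- setdiff(unique(as.vector(object@labels)), 0L)
    if ("0" %in% names(object@regionNames))
      return("label 0 is reserved for background and cannot be named")
    missing <- setdiff(as.character(present), names(object@regionNames))
    if (length(missing) > 0L)
      return(paste0("labels without a region name: ",
                    paste(missing, collapse = ", ")))
    if (length(object@voxelDims) != 3L || any(object@voxelDims <= 0))
      return("voxelDims must be 3 positive values")
    msg <- .checkAffine(object@affine)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' Diffusion gradient scheme
#'
#' Per-volume b-value (s/mm^2) and unit gradient direction. b = 0 entries
#' carry the zero vector.
#'
#' @slot bvals numeric vector of b-values (s/mm^2).
#' @slot bvecs 3 x n matrix of gradient directions (columns).
#' @exportClass DiffusionScheme
setClass("DiffusionScheme",
  representation(bvals = "numeric", bvecs = "matrix"),
  validity = function(object) {
    n <- length(object@bvals)
    if (!is.matrix(object@bvecs) || nrow(object@bvecs) != 3L ||
        ncol(object@bvecs) != n)
      return("bvecs must be a 3 x length(bvals) matrix")
    if (any(!is.finite(object@bvals)) || any(object@bvals < 0))
      return("bvals must be finite and >= 0")
    if (!any(object@bvals == 0))
      return("scheme must contain at least one b = 0 entry")
    norms <- sqrt(colSums(object@bvecs^2))
    bad <- object@bvals > 0 & abs(norms - 1) > 1e-3
    if (any(bad))
      return(sprintf("non-unit gradient vector at volume(s) %s",
                     paste(which(bad), collapse = ", ")))
    TRUE
  })

#' Rigid-motion parameter trace
#'
#' One 6-tuple per volume: three rotations (radians) then three
#' translations (mm), the FSL .par column order.
#'
#' @slot params n x 6 numeric matrix.
#' @exportClass MotionTrace
setClass("MotionTrace",
  representation(params = "matrix"),
  validity = function(object) {
    if (!is.matrix(object@params) || ncol(object@params) != 6L)
      return("params must be an n x 6 matrix")
    if (nrow(object@params) < 1L)
      return("trace must contain at least one volume")
    if (any(!is.finite(object@params)))
      return("motion parameters must be finite")
    TRUE
  })

#' Affine world-to-world transform
#'
#' A 4x4 homogeneous transform in world mm coordinates, e.g. the result
#' of 12-parameter affine registration.
#'
#' @slot matrix 4x4 homogeneous matrix.
#' @slot source identifier of the moving image space.
#' @slot target identifier of the template image space.
#' @slot converged logical; FALSE when registration failed to improve on
#'   the identity and the identity was returned.
#' @exportClass AffineTransform
setClass("AffineTransform",
  representation(matrix = "matrix", source = "character",
                 target = "character", converged = "logical"),
  prototype(source = "source", target = "target", converged = TRUE),
  validity = function(object) {
    msg <- .checkAffine(object@matrix)
    if (!is.null(msg)) return(msg)
    TRUE
  })

#' Per-voxel diffusion tensor field
#'
#' Ordinary-least-squares diffusion tensor fit: per-voxel symmetric
#' tensor coefficients (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), log
#' baseline signal, analysis mask, sorted eigenvalues, and per-voxel
#' quality flags.
#'
#' @slot coeffs 4D array (x, y, z, 6) of tensor coefficients.
#' @slot logS0 3D array of fitted log S0.
#' @slot mask 3D logical analysis mask.
#' @slot evals 4D array (x, y, z, 3), eigenvalues sorted descending.
#' @slot clamped 3D logical; TRUE where a negative eigenvalue was clamped
#'   to zero.
#' @slot degenerate 3D logical; TRUE where the voxel signal was unusable
#'   (all zero) and the voxel is excluded from ROI summaries.
#' @slot voxelDims length-3 numeric (mm).
#' @exportClass TensorField
setClass("TensorField",
  representation(coeffs = "array", logS0 = "array", mask = "array",
                 evals = "array", clamped = "array", degenerate = "array",
                 voxelDims = "numeric"),
  validity = function(object) {
    d <- dim(object@mask)
    if (length(d) != 3L) return("mask must be 3D")
    if (!all(dim(object@coeffs) == c(d, 6L)))
      return("coeffs must be (x, y, z, 6)")
    if (!all(dim(object@evals) == c(d, 3L)))
      return("evals must be (x, y, z, 3)")
    ev <- matrix(object@evals, ncol = 3L)
    inmask <- as.vector(object@mask) & !as.vector(object@degenerate)
    if (any(inmask & !is.finite(ev[, 1L])))
      return("within-mask eigenvalues must be finite")
    if (any(ev[inmask, 1L] < ev[inmask, 2L] - 1e-12) ||
        any(ev[inmask, 2L] < ev[inmask, 3L] - 1e-12))
      return("eigenvalues must be sorted descending")
    TRUE
  })

#' Scalar diffusion map (FA or MD)
#'
#' @slot values 3D numeric array.
#' @slot mask 3D logical; where the map is defined.
#' @slot metric "FA" or "MD".
#' @slot voxelDims length-3 numeric (mm).
#' @exportClass ScalarMap
setClass("ScalarMap",
  representation(values = "array", mask = "array", metric = "character",
                 voxelDims = "numeric"),
  validity = function(object) {
    if (!all(dim(object@values) == dim(object@mask)))
      return("values and mask dimensions differ")
    if (!object@metric %in% c("FA", "MD"))
      return("metric must be 'FA' or 'MD'")
    if (object@metric == "FA") {
      v <- object@values[object@mask]
      if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
        return("FA values must lie in [0, 1] within the mask")
    }
    TRUE
  })

#' Subject x condition x metric value table
#'
#' Long-format table of metric values feeding ANOVA / ICC reliability
#' analysis. A complete subject-by-condition crossing is required for ICC
#' but not enforced here; `metricReport` checks completeness per metric.
#'
#' @slot data data.frame with columns subject, condition, metric, value.
#' @exportClass MetricTable
setClass("MetricTable",
  representation(data = "data.frame"),
  validity = function(object) {
    need <- c("subject", "condition", "metric", "value")
    if (!all(need %in% names(object@data)))
      return(paste("data must have columns:", paste(need, collapse = ", ")))
    if (!is.numeric(object@data$value))
      return("value column must be numeric")
    if (anyDuplicated(object@data[c("subject", "condition", "metric")]))
      return("duplicate (subject, condition, metric) rows")
    TRUE
  })

## ---- small result containers ----

#' Global intensity normalization result
#' @slot scale the applied scaling factor (dimensionless).
#' @slot inputMean whole-brain mean intensity of the input.
#' @slot referenceMean target mean intensity.
#' @exportClass NormalizationResult
setClass("NormalizationResult",
  representation(scale = "numeric", inputMean = "numeric",
                 referenceMean = "numeric"),
  validity = function(object) {
    if (object@scale <= 0) return("scale must be > 0")
    if (abs(object@scale * object@inputMean - object@referenceMean) >
        1e-9 * abs(object@referenceMean))
      return("scale * inputMean must equal referenceMean")
    TRUE
  })

#' Affine scale/skew/rotation decomposition
#'
#' Factorization L = R S K of the linear part of an affine transform:
#' R a rotation, S = diag(sx, sy, sz) positive stretch factors, K a unit
#' upper-triangular skew.
#'
#' @slot scales length-3 positive numeric (sx, sy, sz).
#' @slot skews length-3 numeric (kxy, kxz, kyz).
#' @slot rotation 3x3 rotation matrix.
#' @slot determinant determinant of the linear part.
#' @exportClass ScaleDecomposition
setClass("ScaleDecomposition",
  representation(scales = "numeric", skews = "numeric", rotation = "matrix",
                 determinant = "numeric"),
  validity = function(object) {
    if (length(object@scales) != 3L || any(object@scales <= 0))
      return("scales must be 3 positive values")
    if (object@determinant > 0 &&
        abs(prod(object@scales) - object@determinant) >
          1e-9 * abs(object@determinant))
      return("product of scales must equal the determinant")
    TRUE
  })

#' Temporal SNR result
#' @slot tsnr temporal mean / temporal sd of the ROI-mean time course.
#' @slot timecourse the ROI-mean time course.
#' @slot temporalMean,temporalSd its mean and sample sd.
#' @slot nVoxels,nTimepoints ROI size and series length.
#' @exportClass TsnrResult
setClass("TsnrResult",
  representation(tsnr = "numeric", timecourse = "numeric",
                 temporalMean = "numeric", temporalSd = "numeric",
                 nVoxels = "integer", nTimepoints = "integer"),
  validity = function(object) {
    if (object@temporalSd > 0 &&
        abs(object@tsnr - object@temporalMean / object@temporalSd) >
          1e-9 * max(1, abs(object@tsnr)))
      return("tsnr must equal temporalMean / temporalSd")
    TRUE
  })

#' One-way / summary ANOVA result
#' @slot F F statistic.
#' @slot dfBetween,dfWithin numerator and denominator degrees of freedom.
#' @slot p p-value from the F distribution.
#' @slot mode "one-way" or "from-summary".
#' @exportClass AnovaResult
setClass("AnovaResult",
  representation(F = "numeric", dfBetween = "numeric", dfWithin = "numeric",
                 p = "numeric", mode = "character"),
  validity = function(object) {
    if (!is.finite(object@F) || object@F < 0) return("F must be >= 0")
    TRUE
  })

#' Intraclass correlation result
#'
#' Shrout-Fleiss consistency ICC(3,1): (BMS - EMS) / (BMS + (k-1) EMS)
#' with BMS the between-subject mean square and EMS the two-way residual
#' mean square. The raw value is retained; the reported value is clipped
#' to [0, 1].
#'
#' @slot icc clipped ICC in [0, 1] (NA when undefined).
#' @slot iccRaw unclipped value.
#' @slot bms between-subject mean square.
#' @slot ems residual (error) mean square.
#' @slot k number of conditions.
#' @slot defined FALSE when BMS = EMS = 0 (all cells equal).
#' @exportClass IccResult
setClass("IccResult",
  representation(icc = "numeric", iccRaw = "numeric", bms = "numeric",
                 ems = "numeric", k = "integer", defined = "logical"))

#' Background QC region bounds
#'
#' Closed 1-based integer intervals [lo, hi] on each axis for the
#' anterior-to-head and superior-to-eye background regions used by the
#' T1 motion screening ratio.
#'
#' @slot anterior 3x2 integer matrix, rows x/y/z, columns lo/hi.
#' @slot superior 3x2 integer matrix.
#' @exportClass QcRoiBounds
setClass("QcRoiBounds",
  representation(anterior = "matrix", superior = "matrix"),
  validity = function(object) {
    for (nm in c("anterior", "superior")) {
      b <- slot(object, nm)
      if (!all(dim(b) == c(3L, 2L)))
        return(sprintf("%s must be a 3x2 matrix", nm))
      if (any(b[, 2L] < b[, 1L]))
        return(sprintf("%s has hi < lo", nm))
      if (any(b[, 1L] < 1L))
        return(sprintf("%s bounds are 1-based and must be >= 1", nm))
    }
    TRUE
  })
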