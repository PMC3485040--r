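#' Accessors for mriqa imaging objects
#'
#' Standard accessors for the voxel lattice, affine, voxel dimensions,
#' repetition time, labels and gradient table of the core classes.
#'
#' @param x an mriqa object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("imageAffine", function(x) standardGeneric("imageAffine"))

#' @rdname accessors
#' @export
setGeneric("voxelDims", function(x) standardGeneric("voxelDims"))

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))

#' @rdname accessors
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))

#' @rdname accessors
#' @export
setGeneric("motionParams", function(x) standardGeneric("motionParams"))

#' @rdname accessors
#' @export
setGeneric("transformMatrix", function(x) standardGeneric("transformMatrix"))

#' @rdname accessors
#' @export
setGeneric("metricData", function(x) standardGeneric("metricData"))

setMethod("voxels", "MriImage3D", function(x) x@voxels)
setMethod("voxels", "MriImage4D", function(x) x@voxels)
setMethod("imageAffine", "MriImage3D", function(x) x@affine)
setMethod("imageAffine", "MriImage4D", function(x) x@affine)
setMethod("imageAffine", "LabelMap", function(x) x@affine)
setMethod("voxelDims", "MriImage3D", function(x) x@voxelDims)
setMethod("voxelDims", "MriImage4D", function(x) x@voxelDims)
setMethod("voxelDims", "LabelMap", function(x) x@voxelDims)
setMethod("repetitionTime", "MriImage4D", function(x) x@tr)
setMethod("labelArray", "LabelMap", function(x) x@labels)
setMethod("regionNames", "LabelMap", function(x) x@regionNames)
setMethod("bValues", "DiffusionScheme", function(x) x@bvals)
setMethod("bVectors", "DiffusionScheme", function(x) x@bvecs)
setMethod("motionParams", "MotionTrace", function(x) x@params)
setMethod("transformMatrix", "AffineTransform", function(x) x@matrix)
setMethod("metricData", "MetricTable", function(x) x@data)

setMethod("show", "MriImage3D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("MriImage3D: %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], object@voxelDims[1], object@voxelDims[2],
              object@voxelDims[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "MriImage4D", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(
    "MriImage4D: %d x %d x %d x %d, %.3g x %.3g x %.3g mm, TR %.3g s\n",
    d[1], d[2], d[3], d[4], object@voxelDims[1], object@voxelDims[2],
    object@voxelDims[3], object@tr))
})

setMethod("show", "LabelMap", function(object) {
  labs <- sort(setdiff(unique(as.vector(object@labels)), 0L))
  cat(sprintf("LabelMap: %s voxels, %d region(s)\n",
              paste(dim(object@labels), collapse = " x "), length(labs)))
  for (l in labs)
    cat(sprintf("  %d: %s (%d voxels)\n", l,
                object@regionNames[[as.character(l)]],
                sum(object@labels == l)))
})

setMethod("show", "DiffusionScheme", function(object) {
  cat(sprintf("DiffusionScheme: %d volumes (%d b=0, %d weighted), b max %g s/mm^2\n",
              length(object@bvals), sum(object@bvals == 0),
              sum(object@bvals > 0), max(object@bvals)))
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace: %d volumes\n", nrow(object@params)))
})

setMethod("show", "AffineTransform", function(object) {
  cat(sprintf("AffineTransform: %s -> %s (converged: %s)\n",
              object@source, object@target, object@converged))
  print(round(object@matrix, 6))
})

setMethod("show", "ScaleDecomposition", function(object) {
  cat(sprintf("ScaleDecomposition: scales (%.4f, %.4f, %.4f), det %.4f\n",
              object@scales[1], object@scales[2], object@scales[3],
              object@determinant))
})

setMethod("show", "TsnrResult", function(object) {
  cat(sprintf("TsnrResult: tSNR %.1f (mean %.2f / sd %.3f; %d voxels, %d volumes)\n",
              object@tsnr, object@temporalMean, object@temporalSd,
              object@nVoxels, object@nTimepoints))
})

setMethod("show", "AnovaResult", function(object) {
  cat(sprintf("ANOVA (%s): F(%g, %g) = %.3f, p = %.4g\n", object@mode,
              object@dfBetween, object@dfWithin, object@F, object@p))
})

setMethod("show", "IccResult", function(object) {
  if (!object@defined) {
    cat("ICC: undefined (no variance in the table)\n")
  } else {
    cat(sprintf("ICC(3,1) consistency: %.3f (raw %.3f; BMS %.4g, EMS %.4g, k %d)\n",
                object@icc, object@iccRaw, object@bms, object@ems, object@k))
  }
})

setMethod("show", "MetricTable", function(object) {
  d <- object@data
  cat(sprintf("MetricTable: %d values, %d subject(s) x %d condition(s), %d metric(s)\n",
              nrow(d), length(unique(d$subject)),
              length(unique(d$condition)), length(unique(d$metric))))
})

setMethod("show", "TensorField", function(object) {
  cat(sprintf("TensorField: %s lattice, %d voxels in mask (%d clamped, %d degenerate)\n",
              paste(dim(object@mask), collapse = " x "), sum(object@mask),
              sum(object@clamped), sum(object@degenerate)))
})

setMethod("show", "ScalarMap", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("ScalarMap (%s): %d in-mask voxels, range [%.4g, %.4g]\n",
              object@metric, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})
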