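.defaultAffine <- function(voxelDims) {
  a <- diag(c(voxelDims, 1))
  a
}

#' Construct imaging objects
#'
#' Low-level constructors for the core classes. `affine = NULL` uses a
#' diagonal voxel-to-world matrix built from `voxelDims` with the origin
#' at voxel (0, 0, 0).
#'
#' @param voxels numeric array (3D or 4D).
#' @param voxelDims length-3 voxel dimensions (mm).
#' @param affine 4x4 voxel-to-world matrix, or NULL.
#' @param tr repetition time (s), 4D only.
#' @return An object of the corresponding class.
#' @examples
#' img <- mriImage3D(array(rnorm(8), c(2, 2, 2)))
#' voxelDims(img)
#' @export
mriImage3D <- function(voxels, voxelDims = c(1, 1, 1), affine = NULL) {
  if (is.null(affine)) affine <- .defaultAffine(voxelDims)
  storage.mode(voxels) <- "double"
  new("MriImage3D", voxels = voxels, affine = affine,
      voxelDims = as.numeric(voxelDims))
}

#' @rdname mriImage3D
#' @export
mriImage4D <- function(voxels, voxelDims = c(1, 1, 1), tr = 1, affine = NULL) {
  if (is.null(affine)) affine <- .defaultAffine(voxelDims)
  storage.mode(voxels) <- "double"
  new("MriImage4D", voxels = voxels, affine = affine,
      voxelDims = as.numeric(voxelDims), tr = as.numeric(tr))
}

#' @rdname mriImage3D
#' @param labels 3D integer array of region labels (0 = background).
#' @param regionNames named character vector mapping label integers
#'   (as strings) to region names.
#' @export
labelMap <- function(labels, regionNames = NULL, voxelDims = c(1, 1, 1),
                     affine = NULL) {
  if (is.null(affine)) affine <- .defaultAffine(voxelDims)
  storage.mode(labels) <- "integer"
  if (is.null(regionNames)) {
    labs <- sort(setdiff(unique(as.vector(labels)), 0L))
    regionNames <- stats::setNames(paste0("region", labs), as.character(labs))
  }
  new("LabelMap", labels = labels, regionNames = regionNames,
      affine = affine, voxelDims = as.numeric(voxelDims))
}

#' @rdname mriImage3D
#' @param bvals per-volume b-values (s/mm^2).
#' @param bvecs 3 x n matrix of gradient directions (columns).
#' @export
diffusionScheme <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  dimnames(bvecs) <- NULL
  bvecs[, bvals == 0] <- 0
  new("DiffusionScheme", bvals = as.numeric(bvals), bvecs = bvecs)
}

#' @rdname mriImage3D
#' @param params n x 6 matrix: 3 rotations (rad) then 3 translations (mm).
#' @export
motionTrace <- function(params) {
  params <- as.matrix(params)
  colnames(params) <- c("rx", "ry", "rz", "tx", "ty", "tz")
  new("MotionTrace", params = params)
}

#' @rdname mriImage3D
#' @param matrix 4x4 homogeneous world-to-world transform.
#' @param source,target identifiers for the moving and template spaces.
#' @param converged logical convergence flag.
#' @export
affineTransform <- function(matrix, source = "source", target = "target",
                            converged = TRUE) {
  new("AffineTransform", matrix = matrix, source = source, target = target,
      converged = converged)
}

#' @rdname mriImage3D
#' @param data data.frame with columns subject, condition, metric, value.
#' @export
metricTable <- function(data) {
  data$subject <- as.character(data$subject)
  data$condition <- as.character(data$condition)
  data$metric <- as.character(data$metric)
  new("MetricTable", data = as.data.frame(data))
}
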