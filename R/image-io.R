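#' Read a NIfTI-1 image
#'
#' Reads a 3D or 4D NIfTI-1 file into an [MriImage3D] / [MriImage4D].
#' Intensity scaling (scl_slope / scl_inter) is applied, voxel values are
#' promoted to doubles, the voxel-to-world affine is taken from the
#' sform/qform, and for 4D files the repetition time is read from
#' pixdim[4]. NIfTI-2 files are rejected.
#'
#' @param path path to a .nii or .nii.gz file.
#' @return An [MriImage3D] or [MriImage4D].
#' @seealso [writeNiftiImage()], [readLabelMap()]
#' @export
readNiftiImage <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  .checkNifti1Magic(path)
  img <- RNifti::readNifti(path)
  hdr <- RNifti::niftiHeader(img)
  a <- as.array(img)
  a <- array(as.vector(a), dim(a))  # drop niftiImage attributes
  nd <- length(dim(a))
  .stopIf(!nd %in% c(3L, 4L), "expected a 3D or 4D image, got %dD", nd)
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4L, 4L)
  vd <- abs(hdr$pixdim[2:4])
  if (any(vd <= 0)) vd <- sqrt(colSums(affine[1:3, 1:3]^2))
  .stopIf(any(vd <= 0), "zero voxel dimension in %s", path)
  if (nd == 3L) {
    mriImage3D(a, voxelDims = vd, affine = affine)
  } else {
    tr <- hdr$pixdim[5]
    if (!is.finite(tr) || tr <= 0) {
      warning("missing repetition time in header; using 1 s")
      tr <- 1
    }
    mriImage4D(a, voxelDims = vd, tr = tr, affine = affine)
  }
}

# NIfTI-1 files open with sizeof_hdr = 348 (either endianness); NIfTI-2
# uses 540. Anything else is not a NIfTI payload.
.checkNifti1Magic <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  first <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (length(first) == 0L) stop("not a NIfTI-1 file (empty): ", path)
  swapped <- readBin(writeBin(first, raw()), "integer", size = 4L,
                     endian = "big")
  if (first == 540L || swapped == 540L)
    stop("NIfTI-2 is not supported; convert to NIfTI-1: ", path)
  if (first != 348L && swapped != 348L)
    stop("not a NIfTI-1 file: ", path)
  invisible(TRUE)
}

#' Write a NIfTI-1 image
#'
#' Writes an [MriImage3D] (float32), [MriImage4D] (float32) or [LabelMap]
#' (int32) to a NIfTI-1 file, storing the affine as the sform/qform and,
#' for 4D images, the repetition time in pixdim[4].
#'
#' @param image the object to write.
#' @param path output path (.nii or .nii.gz).
#' @return Invisibly, `path`.
#' @export
writeNiftiImage <- function(image, path) {
  if (is(image, "LabelMap")) {
    arr <- labelArray(image); dt <- "int32"
    vd <- voxelDims(image); affine <- imageAffine(image); tr <- NULL
  } else if (is(image, "MriImage3D")) {
    arr <- voxels(image); dt <- "float"
    vd <- voxelDims(image); affine <- imageAffine(image); tr <- NULL
  } else if (is(image, "MriImage4D")) {
    arr <- voxels(image); dt <- "float"
    vd <- voxelDims(image); affine <- imageAffine(image)
    tr <- repetitionTime(image)
  } else {
    stop("cannot write object of class ", class(image))
  }
  nif <- RNifti::asNifti(arr)
  RNifti::sform(nif) <- structure(affine, code = 2L)
  nif$pixdim <- c(1, vd, if (is.null(tr)) 1 else tr, 0, 0, 0)
  ok <- try(RNifti::writeNifti(nif, path, datatype = dt), silent = TRUE)
  if (inherits(ok, "try-error") || !file.exists(path))
    stop("could not write NIfTI file: ", path)
  invisible(path)
}

#' Read an integer label map
#'
#' Reads a NIfTI-1 volume of integer region labels (0 = background).
#'
#' @param path path to the label NIfTI file.
#' @param regionNames optional named character vector mapping label
#'   integers (as strings) to region names; autogenerated when NULL.
#' @return A [LabelMap].
#' @export
readLabelMap <- function(path, regionNames = NULL) {
  img <- readNiftiImage(path)
  .stopIf(!is(img, "MriImage3D"), "label map must be 3D: %s", path)
  labs <- round(voxels(img))
  .stopIf(max(abs(labs - voxels(img))) > 1e-6,
          "non-integer values in label map %s", path)
  labelMap(labs, regionNames = regionNames, voxelDims = voxelDims(img),
           affine = imageAffine(img))
}

#' Read FSL-style bval/bvec files
#'
#' Parses whitespace-delimited b-value and gradient-direction text files.
#' The bvec table may be 3 x N (rows are x/y/z components, the FSL
#' dialect) or N x 3; the layout is auto-detected from the shape, with an
#' ambiguous 3 x 3 table read as rows-as-components. b = 0 entries are
#' assigned the zero vector; every nonzero direction must be unit length
#' within 1e-3.
#'
#' @param bvalPath,bvecPath paths to the two text files.
#' @return A [DiffusionScheme].
#' @export
readBvalsBvecs <- function(bvalPath, bvecPath) {
  .stopIf(!file.exists(bvalPath), "file not found: %s", bvalPath)
  .stopIf(!file.exists(bvecPath), "file not found: %s", bvecPath)
  bvals <- scan(bvalPath, quiet = TRUE)
  tab <- as.matrix(utils::read.table(bvecPath))
  if (nrow(tab) == 3L && ncol(tab) == 3L) {
    message("ambiguous 3x3 bvec table; assuming rows are x/y/z components")
  } else if (nrow(tab) != 3L) {
    .stopIf(ncol(tab) != 3L,
            "bvec table must be 3 x N or N x 3, got %d x %d",
            nrow(tab), ncol(tab))
    tab <- t(tab)
  }
  .stopIf(ncol(tab) != length(bvals),
          "bval/bvec count mismatch: %d b-values, %d directions",
          length(bvals), ncol(tab))
  diffusionScheme(bvals, tab)
}

#' @rdname readBvalsBvecs
#' @param scheme a [DiffusionScheme] to write.
#' @export
writeBvalsBvecs <- function(scheme, bvalPath, bvecPath) {
  cat(paste(format(bValues(scheme), scientific = FALSE, trim = TRUE),
            collapse = " "), "\n", file = bvalPath)
  utils::write.table(bVectors(scheme), bvecPath, row.names = FALSE,
                     col.names = FALSE)
  invisible(NULL)
}

#' Read/write an FSL .mat affine
#'
#' Reads a 4-line, 4-numbers-per-line text affine (the FSL .mat dialect)
#' into an [AffineTransform]. The bottom row must be (0, 0, 0, 1) within
#' 1e-6.
#'
#' @param path path to the text file.
#' @param source,target space identifiers attached to the transform.
#' @return An [AffineTransform].
#' @export
readAffineMat <- function(path, source = "source", target = "target") {
  .stopIf(!file.exists(path), "file not found: %s", path)
  tab <- as.matrix(utils::read.table(path))
  .stopIf(!all(dim(tab) == c(4L, 4L)),
          "affine file must be 4 x 4, got %d x %d", nrow(tab), ncol(tab))
  dimnames(tab) <- NULL
  .stopIf(max(abs(tab[4L, ] - c(0, 0, 0, 1))) > 1e-6,
          "affine bottom row must be (0, 0, 0, 1)")
  affineTransform(tab, source = source, target = target)
}

#' @rdname readAffineMat
#' @param transform an [AffineTransform] to write.
#' @export
writeAffineMat <- function(transform, path) {
  m <- transformMatrix(transform)
  lines <- apply(m, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = "  "))
  writeLines(lines, path)
  invisible(path)
}

#' Read/write rigid-motion parameter files
#'
#' Reads a 6-column whitespace-delimited motion file (FSL .par order:
#' three rotations in radians then three translations in mm), one row
#' per volume.
#'
#' @param path path to the text file.
#' @return A [MotionTrace].
#' @export
readMotionParams <- function(path) {
  .stopIf(!file.exists(path), "file not found: %s", path)
  tab <- as.matrix(utils::read.table(path))
  .stopIf(ncol(tab) != 6L,
          "motion file must have 6 columns per row, got %d", ncol(tab))
  dimnames(tab) <- NULL
  motionTrace(tab)
}

#' @rdname readMotionParams
#' @param trace a [MotionTrace] to write.
#' @export
writeMotionParams <- function(trace, path) {
  utils::write.table(format(motionParams(trace), digits = 17, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
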