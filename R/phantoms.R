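# Synthetic phantoms with known ground truth: a labeled structural
# volume, a BOLD series with programmed tSNR / drift / nuisance
# structure, and a DWI series generated from known diffusion tensors.

# Run expr with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Voxel membership for a phantom region spec (ellipsoid or half-open box).
.rasterizeRegion <- function(dims, affine, r) {
  if (identical(r$type, "box")) {
    grid <- .voxelGrid(dims)
    world <- affine[1:3, 1:3] %*% grid + affine[1:3, 4]
    array(world[1, ] >= r$center[1] - r$semiAxes[1] &
          world[1, ] <  r$center[1] + r$semiAxes[1] &
          world[2, ] >= r$center[2] - r$semiAxes[2] &
          world[2, ] <  r$center[2] + r$semiAxes[2] &
          world[3, ] >= r$center[3] - r$semiAxes[3] &
          world[3, ] <  r$center[3] + r$semiAxes[3], dims)
  } else {
    .ellipsoidMask(dims, affine, r$center, r$semiAxes)
  }
}

# Rayleigh / Rician magnitude: |(s + n1, n2)| with n ~ N(0, sd) per
# quadrature channel — the noise model of magnitude MR images.
.ricianize <- function(s, sd, n) {
  sqrt((s + stats::rnorm(n, 0, sd))^2 + stats::rnorm(n, 0, sd)^2)
}

#' Structural phantom specification
#'
#' Describes a synthetic T1-like volume: labeled regions (ellipsoids or
#' boxes) of known intensity inside an air background carrying
#' magnitude-image (Rayleigh) noise, with an optional anterior ghost
#' emulating motion artifact. Region membership uses voxel centers:
#' ellipsoids by the inequality sum(((x-c)/a)^2) <= 1, boxes by the
#' half-open rule c - h <= x < c + h (so a 10 mm box at 1 mm voxels
#' contains exactly 1000 voxels).
#'
#' @param dims lattice dimensions (3 integers).
#' @param voxelDims voxel size (mm).
#' @param rois list of regions; each a list with fields `label` (positive
#'   integer), `name`, `type` ("ellipsoid" or "box"), `center` (mm, world
#'   coordinates), `semiAxes` (mm; half-widths for boxes), `intensity`.
#' @param bgNoiseSd per-channel noise sd of the air background (Rayleigh
#'   scale).
#' @param ghostAmplitude intensity added to one quadrature channel inside
#'   the ghost region (0 = no ghost).
#' @param ghostRegion 3x2 matrix of closed 1-based voxel bounds for the
#'   ghost, or NULL.
#' @param smoothFwhm optional Gaussian smoothing (mm FWHM) applied to the
#'   noiseless head intensities, for registration-friendly phantoms.
#' @return A `StructuralPhantomSpec` list.
#' @export
structuralPhantomSpec <- function(dims = c(48, 48, 48),
                                  voxelDims = c(1, 1, 1),
                                  rois = NULL,
                                  bgNoiseSd = 2,
                                  ghostAmplitude = 0,
                                  ghostRegion = NULL,
                                  smoothFwhm = 0) {
  if (is.null(rois)) {
    ext <- dims * voxelDims
    rois <- list(
      list(label = 1L, name = "thalamus-like", type = "ellipsoid",
           center = ext / 2, semiAxes = ext * c(0.25, 0.21, 0.17),
           intensity = 900),
      list(label = 2L, name = "putamen-like", type = "ellipsoid",
           center = ext / 2 + c(0.36 * ext[1], 0, 0),
           semiAxes = ext * c(0.08, 0.10, 0.12), intensity = 700))
  }
  for (r in rois) {
    .stopIf(r$label <= 0, "region labels must be positive")
    .stopIf(any(r$intensity < 0), "region intensities must be >= 0")
    lo <- r$center - r$semiAxes; hi <- r$center + r$semiAxes
    .stopIf(any(lo < -0.5 * voxelDims) || any(hi > (dims - 0.5) * voxelDims),
            "region '%s' extends outside the lattice", r$name)
  }
  structure(list(dims = as.integer(dims), voxelDims = voxelDims,
                 rois = rois, bgNoiseSd = bgNoiseSd,
                 ghostAmplitude = ghostAmplitude, ghostRegion = ghostRegion,
                 smoothFwhm = smoothFwhm),
            class = "StructuralPhantomSpec")
}

#' Generate a structural phantom
#'
#' Rasterizes the regions of a [structuralPhantomSpec()] onto the voxel
#' lattice, giving an intensity image plus a ground-truth [LabelMap]
#' whose per-label voxel counts are exact by construction. Overlapping
#' regions are an error (ground-truth volumes must be unambiguous).
#' Deterministic for a fixed seed.
#'
#' @param spec a `StructuralPhantomSpec`.
#' @param seed integer RNG seed.
#' @return A list with elements `image` ([MriImage3D]) and `labels`
#'   ([LabelMap]).
#' @examples
#' ph <- makeStructuralPhantom(structuralPhantomSpec(), seed = 1)
#' roiVolumes(ph$labels)
#' @export
makeStructuralPhantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "StructuralPhantomSpec"))
  dims <- spec$dims
  affine <- .defaultAffine(spec$voxelDims)
  labs <- array(0L, dims)
  intens <- array(0, dims)
  names <- character(0)
  for (r in spec$rois) {
    inr <- .rasterizeRegion(dims, affine, r)
    .stopIf(any(labs[inr] != 0L),
            "region '%s' overlaps another region", r$name)
    labs[inr] <- as.integer(r$label)
    intens[inr] <- r$intensity
    names[as.character(r$label)] <- r$name
  }
  if (spec$smoothFwhm > 0)
    intens <- .smooth3D(intens,
                        rep(spec$smoothFwhm, 3) /
                          (2 * sqrt(2 * log(2))) / spec$voxelDims)
  .withSeed(seed, {
    bg <- labs == 0L
    nbg <- sum(bg)
    if (nbg > 0 && spec$bgNoiseSd > 0) {
      amp <- numeric(nbg)
      if (spec$ghostAmplitude > 0 && !is.null(spec$ghostRegion)) {
        g <- spec$ghostRegion
        grid <- .voxelGrid(dims) + 1L  # 1-based for bounds
        ing <- grid[1, ] >= g[1, 1] & grid[1, ] <= g[1, 2] &
               grid[2, ] >= g[2, 1] & grid[2, ] <= g[2, 2] &
               grid[3, ] >= g[3, 1] & grid[3, ] <= g[3, 2]
        amp <- spec$ghostAmplitude * as.numeric(array(ing, dims)[bg])
      }
      intens[bg] <- intens[bg] + .ricianize(amp, spec$bgNoiseSd, nbg)
    }
  })
  list(image = mriImage3D(intens, voxelDims = spec$voxelDims,
                          affine = affine),
       labels = labelMap(labs, regionNames = names,
                         voxelDims = spec$voxelDims, affine = affine))
}

#' BOLD phantom specification
#'
#' Describes a synthetic resting-state series whose ROI-mean time course
#' is baseline + slow sinusoidal drift + nuisance contributions + shared
#' Gaussian fluctuation, with independent voxel-level noise on top. The
#' shared ("network-coherent") fluctuation is what sets the programmed
#' ROI-mean tSNR = baseline / sharedSd; voxel noise averages down by the
#' ROI size and is second order.
#'
#' @param dims spatial lattice dimensions.
#' @param voxelDims voxel size (mm).
#' @param tr repetition time (s).
#' @param nVolumes number of volumes (>= 8).
#' @param rois list of regions, each a list with `label`, `name`, `type`,
#'   `center`, `semiAxes` (as in [structuralPhantomSpec()]), `baseline`,
#'   `sharedSd` (> 0), `voxelSd`.
#' @param driftAmplitude,driftPeriod slow drift sinusoid amplitude
#'   (signal units) and period (s).
#' @param nuisanceAmplitudes amplitudes of the nuisance series added to
#'   every ROI mean; one smooth standardized series is generated per
#'   amplitude and returned for regression.
#' @return A `BoldPhantomSpec` list.
#' @export
boldPhantomSpec <- function(dims = c(20, 20, 10), voxelDims = c(3, 3, 3),
                            tr = 2.5, nVolumes = 244, rois = NULL,
                            driftAmplitude = 2, driftPeriod = 300,
                            nuisanceAmplitudes = c(1.5, 1)) {
  if (is.null(rois)) {
    rois <- list(list(label = 1L, name = "network", type = "ellipsoid",
                      center = dims * voxelDims / 2,
                      semiAxes = c(18, 18, 9),
                      baseline = 700, sharedSd = 1, voxelSd = 2))
  }
  .stopIf(nVolumes < 8, "nVolumes must be >= 8")
  for (r in rois) {
    .stopIf(is.null(r$sharedSd) || r$sharedSd <= 0,
            "sharedSd must be > 0 for region '%s'", r$name)
  }
  structure(list(dims = as.integer(dims), voxelDims = voxelDims, tr = tr,
                 nVolumes = as.integer(nVolumes), rois = rois,
                 driftAmplitude = driftAmplitude, driftPeriod = driftPeriod,
                 nuisanceAmplitudes = nuisanceAmplitudes),
            class = "BoldPhantomSpec")
}

#' Generate a BOLD phantom
#'
#' Builds the 4D series described by a [boldPhantomSpec()] together with
#' its ground-truth [LabelMap], an all-zero [MotionTrace] (the phantom is
#' motion-free), the nuisance regressor matrix to feed
#' [nuisanceRegress()], and the programmed per-ROI tSNR. Deterministic
#' for a fixed seed.
#'
#' @param spec a `BoldPhantomSpec`.
#' @param seed integer RNG seed.
#' @return A list with elements `bold` ([MriImage4D]), `labels`
#'   ([LabelMap]), `motion` ([MotionTrace]), `nuisance` (t x p matrix)
#'   and `truth` (list with per-ROI `tsnr`).
#' @export
makeBoldPhantom <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "BoldPhantomSpec"))
  dims <- spec$dims
  nt <- spec$nVolumes
  affine <- .defaultAffine(spec$voxelDims)
  labs <- array(0L, dims)
  names <- character(0)
  rmasks <- list()
  for (r in spec$rois) {
    inr <- .rasterizeRegion(dims, affine, r)
    .stopIf(any(labs[inr] != 0L),
            "region '%s' overlaps another region", r$name)
    labs[inr] <- as.integer(r$label)
    names[as.character(r$label)] <- r$name
    rmasks[[as.character(r$label)]] <- inr
  }
  tsec <- (seq_len(nt) - 1) * spec$tr
  drift <- spec$driftAmplitude * sin(2 * pi * tsec / spec$driftPeriod)
  .withSeed(seed, {
    p <- length(spec$nuisanceAmplitudes)
    nuis <- matrix(0, nt, p)
    if (p > 0) {
      for (j in seq_len(p)) {
        z <- cumsum(stats::rnorm(nt))      # smooth pseudo-physiological drifts
        z <- (z - mean(z)) / stats::sd(z)
        nuis[, j] <- z
      }
    }
    vox <- array(0, c(dims, nt))
    truth <- list(tsnr = numeric(0))
    for (r in spec$rois) {
      m <- rmasks[[as.character(r$label)]]
      nvox <- sum(m)
      shared <- r$baseline + drift +
        as.vector(nuis %*% spec$nuisanceAmplitudes) +
        stats::rnorm(nt, 0, r$sharedSd)
      block <- matrix(rep(shared, each = nvox), nvox, nt) +
        matrix(stats::rnorm(nvox * nt, 0, r$voxelSd), nvox, nt)
      flat <- matrix(vox, prod(dims), nt)
      flat[as.vector(m), ] <- block
      vox <- array(flat, c(dims, nt))
      truth$tsnr[r$name] <- r$baseline / r$sharedSd
    }
  })
  list(bold = mriImage4D(vox, voxelDims = spec$voxelDims, tr = spec$tr,
                         affine = affine),
       labels = labelMap(labs, regionNames = names,
                         voxelDims = spec$voxelDims, affine = affine),
       motion = motionTrace(matrix(0, nt, 6)),
       nuisance = nuis,
       truth = truth)
}

#' DWI phantom specification
#'
#' Describes a diffusion phantom: per-region symmetric positive-definite
#' diffusion tensors (mm^2/s) inside an empty background, a baseline
#' signal S0, and optional Rician noise. The noiseless signal follows
#' the single-tensor model S = S0 exp(-b g' D g) per volume.
#'
#' @param dims lattice dimensions.
#' @param voxelDims voxel size (mm).
#' @param regions list of regions, each with `label`, `name`, `type`,
#'   `center`, `semiAxes` (as in [structuralPhantomSpec()]) and `D`
#'   (3x3 SPD matrix, mm^2/s).
#' @param s0 baseline signal at b = 0.
#' @param noiseSd per-channel Rician noise sd (0 = noiseless).
#' @return A `DwiPhantomSpec` list.
#' @export
dwiPhantomSpec <- function(dims = c(12, 12, 12), voxelDims = c(2, 2, 2),
                           regions = NULL, s0 = 1000, noiseSd = 0) {
  if (is.null(regions)) {
    regions <- list(
      list(label = 1L, name = "wm-like", type = "ellipsoid",
           center = dims * voxelDims / 2, semiAxes = c(9, 8, 7),
           D = diag(c(1.7, 0.3, 0.2)) * 1e-3))
  }
  for (r in regions) {
    D <- r$D
    .stopIf(!isTRUE(all.equal(D, t(D), tolerance = 1e-12)),
            "tensor for region '%s' is not symmetric", r$name)
    ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
    .stopIf(any(ev <= 0),
            "tensor for region '%s' is not positive definite", r$name)
  }
  structure(list(dims = as.integer(dims), voxelDims = voxelDims,
                 regions = regions, s0 = s0, noiseSd = noiseSd),
            class = "DwiPhantomSpec")
}

#' Generate a DWI phantom
#'
#' Evaluates the single-tensor signal model over a gradient scheme for
#' every region of a [dwiPhantomSpec()]. In noiseless mode the signal is
#' exactly S0 exp(-b g' D g); with `noiseSd > 0` Rician noise is added as
#' the magnitude of two quadrature channels.
#'
#' @param spec a `DwiPhantomSpec`.
#' @param scheme a [DiffusionScheme].
#' @param seed integer RNG seed (used only when noise is on).
#' @return A list with elements `dwi` ([MriImage4D], TR fixed at 1 s) and
#'   `labels` ([LabelMap]).
#' @export
makeDwiPhantom <- function(spec, scheme, seed = 1) {
  stopifnot(inherits(spec, "DwiPhantomSpec"), is(scheme, "DiffusionScheme"))
  dims <- spec$dims
  affine <- .defaultAffine(spec$voxelDims)
  b <- bValues(scheme)
  g <- bVectors(scheme)
  nt <- length(b)
  labs <- array(0L, dims)
  names <- character(0)
  vox <- array(0, c(dims, nt))
  flat <- matrix(0, prod(dims), nt)
  for (r in spec$regions) {
    inr <- .rasterizeRegion(dims, affine, r)
    .stopIf(any(labs[inr] != 0L),
            "region '%s' overlaps another region", r$name)
    labs[inr] <- as.integer(r$label)
    names[as.character(r$label)] <- r$name
    gdg <- colSums(g * (r$D %*% g))         # g' D g per volume
    sig <- spec$s0 * exp(-b * gdg)
    flat[as.vector(inr), ] <- matrix(rep(sig, each = sum(inr)),
                                     sum(inr), nt)
  }
  if (spec$noiseSd > 0) {
    .withSeed(seed, {
      flat <- matrix(.ricianize(as.vector(flat), spec$noiseSd,
                                length(flat)),
                     nrow(flat), nt)
    })
  }
  vox <- array(flat, c(dims, nt))
  list(dwi = mriImage4D(vox, voxelDims = spec$voxelDims, tr = 1,
                        affine = affine),
       labels = labelMap(labs, regionNames = names,
                         voxelDims = spec$voxelDims, affine = affine))
}

#' Resample an image through an affine transform
#'
#' Applies a world-to-world affine to a 3D image by trilinear
#' interpolation: each voxel of the output grid (by default the input's
#' own grid) is mapped through the inverse transform into the input and
#' interpolated; samples outside the field of view are 0.
#'
#' @param image an [MriImage3D].
#' @param transform an [AffineTransform] (or 4x4 matrix) mapping input
#'   world coordinates to output world coordinates.
#' @param reference an [MriImage3D] defining the output grid; defaults to
#'   `image`.
#' @return An [MriImage3D] on the reference grid.
#' @export
applyAffineToImage <- function(image, transform, reference = image) {
  stopifnot(is(image, "MriImage3D"), is(reference, "MriImage3D"))
  A <- if (is(transform, "AffineTransform")) transformMatrix(transform)
       else transform
  .stopIf(abs(det(A[1:3, 1:3])) < 1e-12, "singular transform")
  dims <- dim(voxels(reference))
  M <- solve(imageAffine(image)) %*% solve(A) %*% imageAffine(reference)
  grid <- rbind(.voxelGrid(dims), 1)
  src <- M %*% grid
  vals <- .trilinear(voxels(image), src[1:3, , drop = FALSE])
  mriImage3D(array(vals, dims), voxelDims = voxelDims(reference),
             affine = imageAffine(reference))
}
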