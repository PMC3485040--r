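test_that("a 10 mm box at 1 mm voxels rasterizes to exactly 1 cm^3", {
  spec <- structuralPhantomSpec(
    dims = c(16, 16, 16), voxelDims = c(1, 1, 1),
    rois = list(list(label = 1L, name = "cube", type = "box",
                     center = c(7.5, 7.5, 7.5), semiAxes = c(5, 5, 5),
                     intensity = 100)),
    bgNoiseSd = 1)
  ph <- makeStructuralPhantom(spec, seed = 1)
  expect_equal(sum(labelArray(ph$labels) == 1L), 1000L)
  expect_equal(unname(roiVolumes(ph$labels)["cube"]), 1.000)
})

test_that("ellipsoid rasterization matches a brute-force voxelwise oracle", {
  dims <- c(24, 24, 24); ctr <- c(11, 12, 13); semi <- c(10, 8, 6)
  spec <- structuralPhantomSpec(
    dims = dims, voxelDims = c(1, 1, 1),
    rois = list(list(label = 1L, name = "ell", type = "ellipsoid",
                     center = ctr, semiAxes = semi, intensity = 10)),
    bgNoiseSd = 0)
  ph <- makeStructuralPhantom(spec, seed = 1)
  # independent oracle: triple loop over voxel centers
  cnt <- 0L
  for (i in 0:(dims[1] - 1)) for (j in 0:(dims[2] - 1))
    for (k in 0:(dims[3] - 1)) {
      q <- ((i - ctr[1]) / semi[1])^2 + ((j - ctr[2]) / semi[2])^2 +
        ((k - ctr[3]) / semi[3])^2
      if (q <= 1) cnt <- cnt + 1L
    }
  expect_equal(sum(labelArray(ph$labels) == 1L), cnt)
})

test_that("overlapping regions are rejected", {
  spec <- structuralPhantomSpec(
    dims = c(20, 20, 20), voxelDims = c(1, 1, 1),
    rois = list(
      list(label = 1L, name = "a", type = "ellipsoid",
           center = c(9, 9, 9), semiAxes = c(5, 5, 5), intensity = 1),
      list(label = 2L, name = "b", type = "ellipsoid",
           center = c(12, 9, 9), semiAxes = c(5, 5, 5), intensity = 2)))
  expect_error(makeStructuralPhantom(spec, seed = 1), "overlap")
})

test_that("phantoms are bit-identical for a fixed seed", {
  spec <- structuralPhantomSpec(dims = c(12, 12, 12))
  a <- makeStructuralPhantom(spec, seed = 42)
  b <- makeStructuralPhantom(spec, seed = 42)
  c <- makeStructuralPhantom(spec, seed = 43)
  expect_identical(voxels(a$image), voxels(b$image))
  expect_false(identical(voxels(a$image), voxels(c$image)))
})

test_that("without a ghost the two background regions have equal means", {
  anterior <- rbind(c(2L, 5L), c(2L, 5L), c(2L, 5L))
  superior <- rbind(c(10L, 13L), c(10L, 13L), c(10L, 13L))
  spec <- structuralPhantomSpec(dims = c(16, 16, 16), rois = list(),
                                bgNoiseSd = 2, ghostAmplitude = 0)
  diffs <- vapply(1:20, function(s) {
    ph <- makeStructuralPhantom(spec, seed = s)
    r <- backgroundMotionRatio(ph$image,
                               qcRoiBounds(anterior, superior))
    r$anteriorMean - r$superiorMean
  }, 0)
  # Rayleigh(2) over 64 voxels: se of the mean difference ~ 0.23
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs)), 3 * se + 1e-12)
})

test_that("BOLD phantom honors the requested series length and baseline", {
  spec <- boldPhantomSpec(dims = c(8, 8, 4), nVolumes = 244,
                          rois = list(list(
                            label = 1L, name = "net", type = "ellipsoid",
                            center = c(12, 12, 6), semiAxes = c(10, 10, 5),
                            baseline = 100, sharedSd = 1, voxelSd = 1)),
                          driftAmplitude = 0,
                          nuisanceAmplitudes = numeric(0))
  ph <- makeBoldPhantom(spec, seed = 3)
  expect_equal(dim(voxels(ph$bold))[4], 244L)
  expect_true(all(motionParams(ph$motion) == 0))
  m <- roiTsnr(ph$bold, ph$labels)@timecourse
  # sd(mean) ~ sharedSd/sqrt(244); allow 4 sigma
  expect_lt(abs(mean(m) - 100), 4 / sqrt(244))
})

test_that("programmed ROI-mean tSNR is recovered across seeds", {
  spec <- boldPhantomSpec(dims = c(8, 8, 4), nVolumes = 120,
                          rois = list(list(
                            label = 1L, name = "net", type = "ellipsoid",
                            center = c(12, 12, 6), semiAxes = c(10, 10, 5),
                            baseline = 200, sharedSd = 1, voxelSd = 1)),
                          driftAmplitude = 0,
                          nuisanceAmplitudes = numeric(0))
  vals <- vapply(1:20, function(s) {
    ph <- makeBoldPhantom(spec, seed = s)
    roiTsnr(ph$bold, ph$labels)@tsnr
  }, 0)
  # voxel noise inflates the ROI-mean sd by sqrt(1 + voxelSd^2/(n*sharedSd^2))
  n <- sum(labelArray(makeBoldPhantom(spec, seed = 1)$labels) == 1L)
  expected <- 200 / sqrt(1 + 1 / n)
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("noiseless DWI phantom equals the closed-form signal", {
  sch <- testScheme(nDirs = 6L, nB0 = 1L)
  d <- 0.8e-3
  spec <- dwiPhantomSpec(dims = c(6, 6, 6), voxelDims = c(2, 2, 2),
                         regions = list(list(
                           label = 1L, name = "iso", type = "ellipsoid",
                           center = c(5, 5, 5), semiAxes = c(4, 4, 4),
                           D = diag(rep(d, 3)))),
                         s0 = 500, noiseSd = 0)
  ph <- makeDwiPhantom(spec, sch, seed = 1)
  sel <- as.vector(labelArray(ph$labels) == 1L)
  flat <- matrix(voxels(ph$dwi), ncol = length(bValues(sch)))
  for (t in seq_along(bValues(sch))) {
    expect_equal(unique(flat[sel, t]), 500 * exp(-bValues(sch)[t] * d),
                 tolerance = 1e-12)
  }
  # b = 0 volumes are exactly S0
  expect_true(all(flat[sel, bValues(sch) == 0] == 500))
})

test_that("anisotropic DWI signals match a per-voxel matrix-product oracle", {
  sch <- testScheme(nDirs = 6L, nB0 = 1L)
  D <- randomRotation(9) %*% diag(c(1.6, 0.4, 0.3) * 1e-3) %*%
    t(randomRotation(9))
  D <- (D + t(D)) / 2
  spec <- dwiPhantomSpec(dims = c(5, 5, 5), voxelDims = c(2, 2, 2),
                         regions = list(list(
                           label = 1L, name = "wm", type = "ellipsoid",
                           center = c(4, 4, 4), semiAxes = c(3.5, 3.5, 3.5),
                           D = D)),
                         s0 = 1000, noiseSd = 0)
  ph <- makeDwiPhantom(spec, sch, seed = 1)
  flat <- matrix(voxels(ph$dwi), ncol = length(bValues(sch)))
  sel <- which(as.vector(labelArray(ph$labels) == 1L))
  for (t in seq_along(bValues(sch))) {
    g <- bVectors(sch)[, t]
    expected <- 1000 * exp(-bValues(sch)[t] *
                             as.numeric(t(g) %*% D %*% g))
    expect_equal(flat[sel, t], rep(expected, length(sel)),
                 tolerance = 1e-12)
  }
})

test_that("Rician noise mode is deterministic per seed and non-negative", {
  sch <- testScheme()
  spec <- dwiPhantomSpec(dims = c(5, 5, 5), voxelDims = c(2, 2, 2),
                         noiseSd = 10,
                         regions = list(list(
                           label = 1L, name = "r", type = "ellipsoid",
                           center = c(4, 4, 4), semiAxes = c(3.5, 3.5, 3.5),
                           D = diag(rep(1e-3, 3)))))
  a <- makeDwiPhantom(spec, sch, seed = 2)
  b <- makeDwiPhantom(spec, sch, seed = 2)
  expect_identical(voxels(a$dwi), voxels(b$dwi))
  expect_true(all(voxels(a$dwi) >= 0))
})

test_that("non-SPD tensors are rejected", {
  expect_error(dwiPhantomSpec(regions = list(list(
    label = 1L, name = "bad", type = "ellipsoid", center = c(12, 12, 12),
    semiAxes = c(5, 5, 5), D = diag(c(1, 1, -1) * 1e-3)))),
    "positive definite")
})

test_that("affine resampling: identity, integer shifts, inverse composition", {
  # heavily smoothed phantom: double trilinear interpolation error is
  # curvature-limited, so the composition bound below is meaningful
  spec <- structuralPhantomSpec(
    dims = c(40, 40, 40), voxelDims = c(1, 1, 1),
    rois = list(list(label = 1L, name = "head", type = "ellipsoid",
                     center = c(20, 20, 20), semiAxes = c(13, 11, 10),
                     intensity = 900)),
    bgNoiseSd = 0, smoothFwhm = 12)
  img <- makeStructuralPhantom(spec, seed = 2)$image
  # identity
  out <- applyAffineToImage(img, diag(4))
  expect_equal(voxels(out), voxels(img))
  # pure translation by one voxel (1 mm): interior exactly preserved
  Tm <- diag(4); Tm[1, 4] <- 1
  sh <- applyAffineToImage(img, Tm)
  expect_equal(voxels(sh)[2:40, , ], voxels(img)[1:39, , ],
               tolerance = 1e-12)
  # scale up then down recovers the interior within 2% of dynamic range
  S <- diag(c(1.05, 1.05, 1.05, 1))
  back <- applyAffineToImage(applyAffineToImage(img, S), solve(S))
  rng <- diff(range(voxels(img)))
  interior <- 8:33
  err <- max(abs(voxels(back)[interior, interior, interior] -
                   voxels(img)[interior, interior, interior]))
  expect_lt(err, 0.02 * rng)
  expect_error(applyAffineToImage(img, matrix(0, 4, 4)), "singular")
})
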