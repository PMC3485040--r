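boldSeries <- function(mat, tr = 2.5, dims = NULL) {
  # build a 4D image whose (voxel x time) layout equals mat
  if (is.null(dims)) dims <- c(nrow(mat), 1L, 1L)
  mriImage4D(array(mat, c(dims, ncol(mat))), tr = tr)
}

test_that("initial volumes are discarded and the rest preserved", {
  set.seed(31)
  v <- array(rnorm(2 * 2 * 2 * 244), c(2, 2, 2, 244))
  img <- mriImage4D(v, tr = 2.5)
  out <- discardInitialVolumes(img, 4L)
  expect_equal(dim(voxels(out))[4], 240L)
  expect_equal(voxels(out), v[, , , 5:244])
  expect_identical(voxels(discardInitialVolumes(img, 0L)), v)
  expect_error(discardInitialVolumes(img, 244L), "cannot discard")
  # boundary: a near-empty series errors cleanly downstream
  short <- discardInitialVolumes(img, 242L)
  expect_error(roiTsnr(short, array(TRUE, c(2, 2, 2))), "8 timepoints")
})

test_that("brain mask equals phantom support and keeps the largest blob", {
  spec <- structuralPhantomSpec(
    dims = c(16, 16, 16),
    rois = list(list(label = 1L, name = "head", type = "ellipsoid",
                     center = c(7, 7, 7), semiAxes = c(5, 5, 5),
                     intensity = 900)),
    bgNoiseSd = 0)
  ph <- makeStructuralPhantom(spec, seed = 1)
  m <- makeBrainMask(ph$image)
  expect_identical(labelArray(m) != 0L, labelArray(ph$labels) != 0L)
  # two disconnected blobs: only the larger survives
  v <- array(0, c(20, 10, 10))
  v[2:8, 2:8, 2:8] <- 100    # 343 voxels
  v[12:14, 2:4, 2:4] <- 100  # 27 voxels
  m2 <- makeBrainMask(mriImage3D(v))
  expect_equal(sum(labelArray(m2)), 343L)
  expect_true(all(labelArray(m2)[12:14, 2:4, 2:4] == 0L))
  expect_error(makeBrainMask(mriImage3D(array(1, c(4, 4, 4)))), "constant")
})

test_that("mask volume shrinks monotonically as the threshold rises", {
  ph <- headPhantom(seed = 3, dims = c(20, 20, 20))
  fr <- seq(0.2, 0.3, by = 0.025)
  sizes <- vapply(fr, function(f)
    sum(labelArray(makeBrainMask(ph$image, fraction = f))), 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_lt(sizes[length(sizes)], sizes[1])
})

test_that("Gaussian smoothing: identity, conservation, closed form", {
  set.seed(33)
  v <- array(rnorm(8 * 8 * 8 * 3), c(8, 8, 8, 3))
  img <- mriImage4D(v, tr = 2)
  expect_identical(voxels(smoothGaussian(img, 0)), v)
  cons <- smoothGaussian(mriImage4D(array(5, c(8, 8, 8, 2)), tr = 1), 5)
  expect_equal(voxels(cons), array(5, c(8, 8, 8, 2)), tolerance = 1e-12)
  # impulse response vs the closed-form separable Gaussian
  n <- 31L
  imp <- array(0, c(n, n, n))
  ctr <- 16L
  imp[ctr, ctr, ctr] <- 1
  sm <- smoothGaussian(mriImage3D(imp, voxelDims = c(1, 1, 1)), 5)
  sigma <- 5 / (2 * sqrt(2 * log(2)))
  g1 <- function(x) exp(-x^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  xs <- seq_len(n) - ctr
  expected <- outer(g1(xs), g1(xs))  # center plane (z = ctr)
  expect_lt(max(abs(voxels(sm)[, , ctr] - expected * g1(0))), 1e-6)
  expect_error(smoothGaussian(mriImage3D(imp), -1), ">= 0")
})

test_that("high-pass filtering removes drifts and passes signal", {
  nt <- 240L; tr <- 2.5
  tt <- (seq_len(nt) - 1) * tr
  slow <- sin(2 * pi * tt / 300)        # 300 s period: below cutoff
  fast <- sin(2 * pi * tt / 10)         # 10 s period: passband
  img <- boldSeries(rbind(100 + slow, 100 + fast), tr = tr)
  out <- highpassTemporal(img, 150)
  res <- matrix(voxels(out), 2, nt)
  expect_lt(max(abs(res[1, ] - 100)), 0.05 * 1)          # <5% residual
  expect_gt(sd(res[2, ]), 0.95 * sd(fast))               # <5% attenuation
  # temporal mean of white noise is preserved exactly
  set.seed(35)
  wn <- matrix(rnorm(5 * nt), 5, nt) + 50
  out2 <- highpassTemporal(boldSeries(wn, tr = tr), 150)
  expect_equal(rowMeans(matrix(voxels(out2), 5, nt)), rowMeans(wn),
               tolerance = 1e-9)
  expect_error(highpassTemporal(img, 4), "exceed")
})

test_that("nuisance regression projects out regressors, keeps the mean", {
  nt <- 100L
  set.seed(36)
  signal <- 200 + sin(2 * pi * seq_len(nt) / 7)
  # motion orthogonal to the intercept and the signal, so OLS removes
  # exactly the injected 3 x motion component
  raw <- rnorm(nt)
  X0 <- cbind(1, signal - mean(signal))
  motion <- raw - X0 %*% solve(crossprod(X0), crossprod(X0, raw))
  series <- signal + 3 * as.vector(motion)
  img <- boldSeries(rbind(series, rnorm(nt) + 10), tr = 1)
  out <- nuisanceRegress(img, cbind(motion))
  res <- matrix(voxels(out), 2, nt)
  expect_lt(sqrt(mean((res[1, ] - signal)^2)), 1e-6)
  expect_equal(mean(res[1, ]), mean(series), tolerance = 1e-9)
  # a regressor equal to a voxel's demeaned time course flattens it
  out2 <- nuisanceRegress(img, cbind(series - mean(series)))
  res2 <- matrix(voxels(out2), 2, nt)
  expect_equal(res2[1, ], rep(mean(series), nt), tolerance = 1e-9)
  expect_error(nuisanceRegress(img, cbind(rep(0, nt))), "rank")
})

test_that("ROI tSNR is the ROI-mean time-course mean over sd", {
  nt <- 240L
  set.seed(37)
  m <- 700 + rnorm(nt)   # mean ~700, sd ~1 -> tSNR ~700
  mat <- matrix(rep(m, each = 8), 8, nt)
  img <- boldSeries(mat, dims = c(2, 2, 2))
  res <- roiTsnr(img, array(TRUE, c(2, 2, 2)))
  expect_equal(res@tsnr, mean(m) / sd(m), tolerance = 1e-12)
  expect_equal(res@nVoxels, 8L)
  expect_gt(res@tsnr, 400)  # the magnitude of network-level tSNR
  # scale invariance
  res10 <- roiTsnr(boldSeries(mat * 10, dims = c(2, 2, 2)),
                   array(TRUE, c(2, 2, 2)))
  expect_equal(res10@tsnr, res@tsnr, tolerance = 1e-12)
  expect_error(roiTsnr(boldSeries(matrix(1, 4, 50)), array(TRUE, c(4, 1, 1))),
               "constant")
  expect_error(roiTsnr(img, array(FALSE, c(2, 2, 2))), "empty")
})

test_that("preprocessing preserves the ROI mean and removes drift", {
  # ROI = the whole lattice, so spatial smoothing cannot mix in
  # background and the mean-preservation property is exact
  spec <- boldPhantomSpec(dims = c(10, 10, 6), nVolumes = 120,
                          rois = list(list(
                            label = 1L, name = "net", type = "box",
                            center = c(15, 15, 9), semiAxes = c(16, 16, 10),
                            baseline = 500, sharedSd = 2.5, voxelSd = 2)),
                          driftAmplitude = 10, driftPeriod = 300,
                          nuisanceAmplitudes = numeric(0))
  ph <- makeBoldPhantom(spec, seed = 5)
  raw <- discardInitialVolumes(ph$bold, 4L)
  pre <- preprocessBold(ph$bold, discard = 4L, fwhm = 5, highpass = 150)
  rawT <- roiTsnr(raw, ph$labels)
  preT <- roiTsnr(pre, ph$labels)
  expect_lt(abs(preT@temporalMean - rawT@temporalMean) / rawT@temporalMean,
            0.001)
  # drift removal increases tSNR on the motion-free phantom
  expect_gt(preT@tsnr, rawT@tsnr)
})

test_that("programmed tSNR survives the full preprocessing chain", {
  spec <- boldPhantomSpec(dims = c(10, 10, 6), nVolumes = 244,
                          rois = list(list(
                            label = 1L, name = "net", type = "box",
                            center = c(15, 15, 9), semiAxes = c(16, 16, 10),
                            baseline = 500, sharedSd = 2.5, voxelSd = 2)),
                          driftAmplitude = 5, driftPeriod = 300,
                          nuisanceAmplitudes = c(2))
  vals <- vapply(1:20, function(s) {
    ph <- makeBoldPhantom(spec, seed = 100 + s)
    reg <- ph$nuisance[5:244, , drop = FALSE]
    pre <- preprocessBold(ph$bold, discard = 4L, fwhm = 5,
                          highpass = 150, regressors = reg)
    roiTsnr(pre, ph$labels)@tsnr
  }, 0)
  expect_lt(abs(mean(vals) - 200) / 200, 0.10)
})

test_that("maximum adjacent displacement matches brute force", {
  z <- motionTrace(matrix(0, 10, 6))
  expect_equal(maxAdjacentDisplacement(z)$maxTranslation, 0)
  two <- motionTrace(rbind(rep(0, 6), c(0, 0, 0, 0.3, 0, 0.4)))
  expect_equal(maxAdjacentDisplacement(two)$maxTranslation, 0.5)
  set.seed(39)
  m <- matrix(rnorm(60), 10, 6)
  got <- maxAdjacentDisplacement(motionTrace(m))
  # brute-force pairwise scan
  bt <- 0; br <- 0
  for (i in 2:10) {
    bt <- max(bt, sqrt(sum((m[i, 4:6] - m[i - 1, 4:6])^2)))
    br <- max(br, sqrt(sum((m[i, 1:3] - m[i - 1, 1:3])^2)))
  }
  expect_equal(got$maxTranslation, bt, tolerance = 1e-12)
  expect_equal(got$maxRotation, br, tolerance = 1e-12)
  expect_error(maxAdjacentDisplacement(motionTrace(matrix(0, 1, 6))),
               "at least 2")
})
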