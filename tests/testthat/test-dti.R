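test_that("design matrix rows encode the log-linear tensor model", {
  sch <- testScheme(nDirs = 6L, nB0 = 1L)
  X <- buildDesignMatrix(sch)
  expect_equal(X[1, ], c(0, 0, 0, 0, 0, 0, 1))  # b = 0 row
  schX <- diffusionScheme(c(0, rep(1000, 6)),
                          cbind(0, rbind(c(1, 0, 0, 0, 1, 1) /
                                           sqrt(c(1, 1, 1, 1, 2, 2)),
                                         c(0, 1, 0, 1, 0, 1) /
                                           sqrt(c(1, 1, 1, 2, 1, 2)),
                                         c(0, 0, 1, 1, 1, 0) /
                                           sqrt(c(1, 1, 1, 2, 2, 1)))))
  Xx <- buildDesignMatrix(schX)
  expect_equal(Xx[2, ], c(-1000, 0, 0, 0, 0, 0, 1))
  # a 60-direction scheme is full rank with finite conditioning
  X60 <- buildDesignMatrix(testScheme(nDirs = 60L, nB0 = 8L))
  expect_equal(qr(X60)$rank, 7L)
  expect_true(is.finite(kappa(X60)))
  # fewer than 6 unique directions is rank deficient
  expect_error(buildDesignMatrix(diffusionScheme(
    c(0, rep(1000, 5)),
    cbind(0, diag(3)[, c(1, 2, 3, 1, 2)]))), "unique")
})

test_that("noiseless phantom tensors are recovered to 1e-9", {
  sch <- testScheme(nDirs = 12L, nB0 = 2L)
  Dtrue <- diag(c(1.7, 0.3, 0.2) * 1e-3)
  spec <- dwiPhantomSpec(dims = c(8, 8, 8), voxelDims = c(2, 2, 2),
                         regions = list(list(
                           label = 1L, name = "wm", type = "ellipsoid",
                           center = c(7, 7, 7), semiAxes = c(6, 6, 6),
                           D = Dtrue)),
                         s0 = 1000, noiseSd = 0)
  ph <- makeDwiPhantom(spec, sch, seed = 1)
  tf <- fitTensor(ph$dwi, sch, labelArray(ph$labels) != 0L)
  sel <- which(as.vector(tf@mask))
  cf <- matrix(tf@coeffs, ncol = 6)[sel, , drop = FALSE]
  truthVec <- c(Dtrue[1, 1], Dtrue[2, 2], Dtrue[3, 3],
                Dtrue[1, 2], Dtrue[1, 3], Dtrue[2, 3])
  expect_lt(max(abs(sweep(cf, 2, truthVec))), 1e-9)
  # fitted ln S0 equals ln of the phantom S0
  expect_lt(max(abs(tf@logS0[sel] - log(1000))), 1e-9)
  ev <- matrix(tf@evals, ncol = 3)[sel, , drop = FALSE]
  expect_lt(max(abs(ev[, 1] - 1.7e-3)), 1e-9)
  expect_lt(max(abs(ev[, 3] - 0.2e-3)), 1e-9)
})

test_that("isotropic tensors yield equal eigenvalues and zero FA", {
  sch <- testScheme()
  d <- 0.9e-3
  spec <- dwiPhantomSpec(dims = c(6, 6, 6), voxelDims = c(2, 2, 2),
                         regions = list(list(
                           label = 1L, name = "iso", type = "ellipsoid",
                           center = c(5, 5, 5), semiAxes = c(4, 4, 4),
                           D = diag(rep(d, 3)))),
                         noiseSd = 0)
  ph <- makeDwiPhantom(spec, sch, seed = 1)
  tf <- fitTensor(ph$dwi, sch, labelArray(ph$labels) != 0L)
  sel <- which(as.vector(tf@mask))
  ev <- matrix(tf@evals, ncol = 3)[sel, , drop = FALSE]
  expect_lt(max(abs(ev - d)), 1e-9)
  fm <- faMap(tf)
  expect_lt(max(fm@values[fm@mask]), 1e-6)
})

test_that("FA endpoints, bounds, and scale invariance", {
  expect_equal(fa(1, 1, 1), 0)
  expect_equal(fa(1, 0, 0), 1)
  # derived arithmetic oracle for the WM-like triple
  l <- c(1.7, 0.3, 0.2) * 1e-3
  lb <- mean(l)
  direct <- sqrt(1.5) * sqrt(sum((l - lb)^2)) / sqrt(sum(l^2))
  expect_equal(fa(l[1], l[2], l[3]), direct, tolerance = 1e-12)
  expect_equal(round(direct, 3), 0.836)
  # property: FA in [0, 1] and invariant under eigenvalue scaling
  set.seed(41)
  for (i in 1:50) {
    tr3 <- sort(runif(3, 0, 2), decreasing = TRUE)
    v <- fa(tr3[1], tr3[2], tr3[3])
    expect_gte(v, 0); expect_lte(v, 1)
    expect_equal(fa(5 * tr3[1], 5 * tr3[2], 5 * tr3[3]), v,
                 tolerance = 1e-12)
  }
  expect_true(is.na(fa(0, 0, 0)))
})

test_that("MD is the eigenvalue mean and the trace identity holds", {
  expect_equal(md(1, 1, 1), 1)
  expect_equal(md(1.7e-3, 0.3e-3, 0.2e-3), 0.7333333333e-3,
               tolerance = 1e-10)
  # MD scales linearly
  expect_equal(md(3.4e-3, 0.6e-3, 0.4e-3),
               2 * md(1.7e-3, 0.3e-3, 0.2e-3), tolerance = 1e-12)
  # trace identity on a fitted tensor
  sch <- testScheme()
  D <- randomRotation(17) %*% diag(c(1.5, 0.5, 0.3) * 1e-3) %*%
    t(randomRotation(17))
  D <- (D + t(D)) / 2
  spec <- dwiPhantomSpec(dims = c(5, 5, 5), voxelDims = c(2, 2, 2),
                         regions = list(list(
                           label = 1L, name = "r", type = "ellipsoid",
                           center = c(4, 4, 4), semiAxes = c(3.5, 3.5, 3.5),
                           D = D)),
                         noiseSd = 0)
  ph <- makeDwiPhantom(spec, sch, seed = 1)
  tf <- fitTensor(ph$dwi, sch, labelArray(ph$labels) != 0L)
  sel <- which(as.vector(tf@mask))[1]
  cf <- matrix(tf@coeffs, ncol = 6)[sel, ]
  ev <- matrix(tf@evals, ncol = 3)[sel, ]
  expect_equal(md(ev[1], ev[2], ev[3]), sum(cf[1:3]) / 3,
               tolerance = 1e-12)
})

test_that("full pipeline identity: phantom FA/MD reproduced to 1e-9", {
  sch <- testScheme(nDirs = 12L, nB0 = 2L)
  lambdas <- c(1.6, 0.35, 0.25) * 1e-3
  D <- randomRotation(23) %*% diag(lambdas) %*% t(randomRotation(23))
  D <- (D + t(D)) / 2
  spec <- dwiPhantomSpec(dims = c(7, 7, 7), voxelDims = c(2, 2, 2),
                         regions = list(list(
                           label = 1L, name = "wm", type = "ellipsoid",
                           center = c(6, 6, 6), semiAxes = c(5, 5, 5),
                           D = D)),
                         noiseSd = 0)
  ph <- makeDwiPhantom(spec, sch, seed = 1)
  tf <- fitTensor(ph$dwi, sch, labelArray(ph$labels) != 0L)
  faTruth <- fa(lambdas[1], lambdas[2], lambdas[3])
  mdTruth <- md(lambdas[1], lambdas[2], lambdas[3])
  fm <- faMap(tf); mm <- mdMap(tf)
  expect_lt(max(abs(fm@values[fm@mask] - faTruth)), 1e-9)
  expect_lt(max(abs(mm@values[mm@mask] - mdTruth)), 1e-9)
})

test_that("ROI summaries match brute-force masked statistics", {
  set.seed(43)
  v <- array(runif(4^3, 0.3, 0.6), c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  sm <- new("ScalarMap", values = v, mask = mask, metric = "FA",
            voxelDims = c(2, 2, 2))
  roi <- array(runif(4^3) < 0.5, c(4, 4, 4))
  got <- roiMeanMetric(sm, roi)
  expect_equal(got$mean, mean(v[roi]), tolerance = 1e-12)
  expect_equal(got$sd, sd(v[roi]), tolerance = 1e-12)
  expect_equal(got$n, sum(roi))
  # uniform map: mean equal to the constant, sd 0
  smU <- new("ScalarMap", values = array(0.44, c(4, 4, 4)), mask = mask,
             metric = "FA", voxelDims = c(2, 2, 2))
  gotU <- roiMeanMetric(smU, mask)
  expect_equal(gotU$mean, 0.44)
  expect_equal(gotU$sd, 0)
  # single-voxel ROI: sd undefined -> 0 with flag
  one <- array(FALSE, c(4, 4, 4)); one[2, 2, 2] <- TRUE
  g1 <- roiMeanMetric(sm, one)
  expect_equal(g1$n, 1L)
  expect_false(g1$sdDefined)
  expect_error(roiMeanMetric(sm, array(FALSE, c(4, 4, 4))), "intersect")
})

test_that("ROI-mean FA bias stays small under 2% Rician noise", {
  sch <- testScheme(nDirs = 60L, nB0 = 8L)
  lambdas <- c(1.5, 0.4, 0.3) * 1e-3
  faTruth <- fa(lambdas[1], lambdas[2], lambdas[3])
  spec <- dwiPhantomSpec(dims = c(6, 6, 6), voxelDims = c(2, 2, 2),
                         regions = list(list(
                           label = 1L, name = "wm", type = "ellipsoid",
                           center = c(5, 5, 5), semiAxes = c(4.5, 4.5, 4.5),
                           D = diag(lambdas))),
                         s0 = 1000, noiseSd = 20)
  means <- vapply(1:20, function(s) {
    ph <- makeDwiPhantom(spec, sch, seed = s)
    tf <- fitTensor(ph$dwi, sch, labelArray(ph$labels) != 0L)
    roiMeanMetric(faMap(tf), labelArray(ph$labels) == 1L)$mean
  }, 0)
  expect_lt(abs(mean(means) - faTruth), 0.02)
})
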