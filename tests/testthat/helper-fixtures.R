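# Shared in-code fixtures: small phantoms and gradient schemes built at
# test time.

# Smooth single-region head phantom suitable for registration.
headPhantom <- function(seed = 1, dims = c(28, 28, 28)) {
  spec <- structuralPhantomSpec(
    dims = dims, voxelDims = c(2, 2, 2),
    rois = list(list(label = 1L, name = "head", type = "ellipsoid",
                     center = dims, semiAxes = dims * 2 * c(0.34, 0.28, 0.22),
                     intensity = 900)),
    bgNoiseSd = 2, smoothFwhm = 6)
  makeStructuralPhantom(spec, seed = seed)
}

# Deterministic gradient scheme: the canonical six-direction set for
# nDirs = 6, a spherical spiral otherwise.
testScheme <- function(nDirs = 12L, nB0 = 2L, b = 1000) {
  if (nDirs == 6L) {
    g <- cbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1),
               c(1, -1, 0), c(1, 0, -1), c(0, 1, -1)) / sqrt(2)
  } else {
    i <- seq_len(nDirs)
    z <- (2 * i - nDirs - 1) / nDirs
    th <- i * pi * (3 - sqrt(5))
    g <- rbind(sqrt(1 - z^2) * cos(th), sqrt(1 - z^2) * sin(th), z)
  }
  diffusionScheme(c(rep(0, nB0), rep(b, nDirs)),
                  cbind(matrix(0, 3, nB0), g))
}

# Random rotation matrix from a fixed seed (QR of a Gaussian matrix).
randomRotation <- function(seed) {
  set.seed(seed)
  qrd <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
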