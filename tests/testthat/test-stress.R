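test_that("the rectangle solid angle has the right limits and matches quadrature", {
  a <- 19e-3; b <- 4e-3
  expect_equal(loveOmega(0, 0, 1e-9, a, b), 2 * pi, tolerance = 1e-6)
  expect_lt(loveOmega(1, 1, 1e-9, a, b), 1e-8)
  expect_error(loveOmega(0, 0, 0, a, b), "z must be > 0")
  # generic interior points against the solid-angle integral z/R^3 dA
  set.seed(12)
  for (i in 1:4) {
    x <- runif(1, -0.03, 0.03); y <- runif(1, -0.01, 0.01)
    z <- runif(1, 3e-3, 0.02) # shallower depths defeat the quadrature oracle
    quad <- pracma::integral2(function(xi, eta)
      z / ((x - xi)^2 + (y - eta)^2 + z^2)^1.5, -a, a, -b, b,
      reltol = 1e-10)$Q
    expect_lt(abs(loveOmega(x, y, z, a, b) - quad), 5e-6)
  }
})

test_that("Love's axial stress equals the surface pressure under the load and scales linearly", {
  a <- 19e-3; b <- 4e-3
  expect_equal(loveSigmaZz(0, 0, 1e-9, a, b, 635), 635, tolerance = 1e-6)
  expect_equal(loveSigmaZz(0.004, 0.001, 0.01, a, b, 0), 0)
  # homogeneous of degree 1 in p; symmetric in x and y
  s1 <- loveSigmaZz(0.006, 0.002, 0.008, a, b, 100)
  expect_equal(loveSigmaZz(0.006, 0.002, 0.008, a, b, 700), 7 * s1)
  expect_equal(loveSigmaZz(-0.006, 0.002, 0.008, a, b, 100), s1)
  expect_equal(loveSigmaZz(0.006, -0.002, 0.008, a, b, 100), s1)
  # |sigma| decreases with depth on the central axis
  zs <- seq(1e-3, 0.03, length.out = 20)
  expect_true(all(diff(loveSigmaZz(0, 0, zs, a, b, 635)) < 0))
})

test_that("Love's solution agrees with the Boussinesq quadrature oracle below 0.5%", {
  a <- 19e-3; b <- 4e-3; p <- 635
  xs <- seq(-0.02, 0.02, length.out = 5)
  zs <- seq(2e-3, 20e-3, length.out = 5)
  worst <- 0
  for (x in xs) for (z in zs) {
    lv <- loveSigmaZz(x, 0, z, a, b, p)
    bo <- boussinesqSigmaZz(x, 0, z, a, b, p, reltol = 1e-9)
    worst <- max(worst, abs(lv - bo) / bo)
  }
  expect_lt(worst, 0.005)
  # far field decays like the equivalent point load 3Fz^3/(2 pi R^5) = 3F/(2 pi z^2)
  zfar <- 0.5
  expect_equal(loveSigmaZz(0, 0, zfar, a, b, p),
               3 * p * 4 * a * b / (2 * pi * zfar^2), tolerance = 3e-3)
})

test_that("two-compressor superposition is symmetric and bottom-weighted correctly", {
  # equal compressors and symmetric geometry: field symmetric about mid-height
  g <- scanGeometry(transducerWidth = 20e-3, transducerDepth = 20e-3,
                    baseWidth = 20e-3, baseDepth = 20e-3,
                    specimenHeight = 20e-3, pixelSize = 1e-3)
  tot <- totalStressField(1, g, c(20, 20))
  expect_equal(tot@sigmaZz, tot@sigmaZz[20:1, ], tolerance = 1e-9)
  # zero force gives a zero field
  expect_equal(max(abs(totalStressField(0, scanGeometry(), c(16, 16))@sigmaZz)),
               0)
  # default phantom geometry: at mid-height the bottom term is the smaller one
  g2 <- scanGeometry(); g2@pixelSize <- 25e-3 / 64
  top <- loveStressField(0.2, g2, c(64, 64))@sigmaZz
  tot2 <- totalStressField(0.2, g2, c(64, 64))@sigmaZz
  bottomPart <- tot2[32, 32] - top[32, 32]
  expect_gt(bottomPart, 0)
  expect_lt(bottomPart, top[32, 32])
})

test_that("the plane-stress baseline is uniform F/A1 and differs most toward the edges", {
  g <- scanGeometry(); g@pixelSize <- 25e-3 / 64
  pl <- planeStressField(0.193, g, c(64, 64))
  expect_equal(unique(as.vector(pl@sigmaZz)), 0.193 / 304e-6, tolerance = 1e-12)
  expect_equal(pl@sigmaZz[1, 32], 635, tolerance = 0.5)
  expect_equal(planeStressField(2 * 0.193, g, c(64, 64))@sigmaZz,
               2 * pl@sigmaZz)
  lv <- loveStressField(0.193, g, c(64, 64))@sigmaZz
  diffmap <- abs(lv - pl@sigmaZz)
  # the deviation from uniform stress grows toward the lateral edges
  expect_gt(diffmap[5, 1], diffmap[5, 32])
  # field magnitude never exceeds the superposition bound
  tot <- totalStressField(0.193, g, c(64, 64))@sigmaZz
  expect_lt(max(tot), 635 * (1 + 304 / 1125) + 1)
})
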