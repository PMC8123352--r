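mkStrain <- function(ezz, exx = NULL, n = 32) {
  z <- matrix(ezz, n, n)
  x <- if (is.null(exx)) matrix(0, n, n) else matrix(exx, n, n)
  mask <- matrix(TRUE, n, n)
  new("StrainField", exx = x, exz = matrix(0, n, n), ezx = matrix(0, n, n),
      ezz = z, validMask = mask, framePair = c(1L, 2L), M = 1L)
}

mkStress <- function(sigma, n = 32) {
  new("StressField", sigmaZz = matrix(sigma, n, n), pressure = sigma,
      geometry = scanGeometry(), assumption = "plane")
}

test_that("the framewise modulus map divides stress by strain with masking", {
  E <- frameModulusMap(mkStrain(-0.1), mkStress(1000))
  expect_equal(unique(as.vector(E)), 10000)
  # below the strain floor: masked
  E2 <- frameModulusMap(mkStrain(-5e-5), mkStress(1000))
  expect_true(all(is.na(E2)))
  # the non-linear correction divides out the stiffening factor exactly
  eps <- 0.1; gamma <- 10
  sig <- 8e3 * eps * exp(3 * gamma * eps^2)
  E3 <- frameModulusMap(mkStrain(-eps), mkStress(sig), gamma = gamma)
  expect_equal(unique(as.vector(E3)), 8e3, tolerance = 1e-12)
})

test_that("mean map averages accepted frames with a count map", {
  m1 <- matrix(1, 4, 4); m2 <- matrix(3, 4, 4)
  m2[1, 1] <- NA
  out <- meanModulusMap(list(m1, m2, m1 * 10), accepted = 1:2)
  expect_equal(out$mean[2, 2], 2)
  expect_equal(out$mean[1, 1], 1) # only one valid frame there
  expect_equal(out$count[1, 1], 1L)
  expect_equal(out$count[2, 2], 2L)
  single <- meanModulusMap(list(m1, m2), accepted = 2)
  expect_equal(single$mean[2, 2], 3)
  expect_error(meanModulusMap(list(m1), integer()), "no accepted frames")
})

test_that("the Poisson map implements the strain ratio with the 3D conversion", {
  # lateral = -axial/3 (2D ratio 1/3) -> incompressible nu = 0.5
  s <- mkStrain(-0.09, exx = 0.03)
  expect_equal(unique(as.vector(poissonMap(s))), 0.5, tolerance = 1e-12)
  # no lateral expansion -> nu = 0
  expect_equal(unique(as.vector(poissonMap(mkStrain(-0.09, 0)))), 0)
  # tiny axial strain is masked
  expect_true(all(is.na(poissonMap(mkStrain(-5e-5, 1e-5)))))
  # report range is clipped to [0, 0.5]
  s2 <- mkStrain(-0.09, exx = 0.05) # nu' = 0.55 -> nu > 1 -> clipped
  expect_true(all(poissonMap(s2) <= 0.5))
})

test_that("ROI masks and summaries report the right statistics", {
  px <- 1e-3
  map <- matrix(2, 20, 20)
  map[, 11:20] <- 6
  rois <- list(roiRect("left", 0, 0, 9.9e-3, 20e-3),
               roiRect("right", 10.1e-3, 0, 20e-3, 20e-3))
  s <- roiSummary(map, rois, px)
  expect_equal(s$median, c(2, 6))
  expect_equal(s$sd, c(0, 0))
  circ <- roiCircle("c", 10e-3, 10e-3, 3e-3)
  msk <- roiMask(circ, c(20, 20), px)
  expect_true(msk[10, 10] && !msk[1, 1])
  expect_error(roiSummary(matrix(NA_real_, 20, 20), rois, px),
               "no valid pixels")
  # default layouts: 1 central region or inclusion + two body regions
  expect_length(defaultRois(c(0.025, 0.025)), 1)
  expect_length(defaultRois(c(0.025, 0.025), c(0.0125, 0.0125), 4e-3), 3)
})
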