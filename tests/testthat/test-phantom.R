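test_that("speckle is deterministic, plateauing and PSF-controlled", {
  a <- makeSpeckle(c(64, 64), 0.15, 1.2, 42)
  b <- makeSpeckle(c(64, 64), 0.15, 1.2, 42)
  expect_identical(a, b)
  expect_false(identical(a, makeSpeckle(c(64, 64), 0.15, 1.2, 43)))
  expect_true(all(a >= 0 & a <= 1))
  # variance of the normalised texture stabilises as density grows
  v <- vapply(c(0.05, 0.2, 1, 4, 8), function(d)
    var(as.vector(makeSpeckle(c(96, 96), d, 1.2, 1))), numeric(1))
  relstep <- abs(diff(v)) / v[-1]
  expect_lt(relstep[length(relstep)], min(relstep[1], 1))
  # psfSigma = 0 keeps raw impulses: many exact zeros
  raw <- makeSpeckle(c(64, 64), 0.05, 0, 2)
  expect_gt(mean(raw == 0), 0.5)
})

test_that("the uniform-stress phantom matches series-spring mechanics", {
  sp <- tinyPhantom(stressModel = "uniform")
  fld <- phantomDisplacementField(sp, 3e-3)
  # homogeneous: ezz = -d/H exactly, everywhere
  expect_equal(unique(round(as.vector(fld$ezz), 12)), round(-3e-3 / 25e-3, 12))
  # strain integrates back to the applied compression per column to 1e-10
  px <- sp@geometry@pixelSize
  colInt <- colSums(-fld$ezz) * px
  expect_lt(max(abs(colInt - 3e-3)), 1e-10)
  # inclusion columns strain less, with the modulus ratio inside the layers
  spI <- tinyPhantom(inclusionE = 2 * 6920, stressModel = "uniform")
  fldI <- phantomDisplacementField(spI, 3e-3)
  n <- spI@imageSize[1]
  centre <- ceiling(n / 2)
  E <- fldI$EMap
  inclRows <- which(E[, centre] > 6920)
  bodyRows <- setdiff(seq_len(n), inclRows)
  inclStrain <- median(-fldI$ezz[inclRows, centre])
  bodyStrain <- median(-fldI$ezz[bodyRows, centre])
  expect_lt(inclStrain, bodyStrain)
  # same-column stress: strain ratio equals the inverse modulus ratio
  # (within the tolerance left by the 1 mm lateral edge smoothing)
  expect_equal(bodyStrain / inclStrain, 2, tolerance = 0.1)
  # per-column integral still equals the applied compression
  expect_lt(max(abs(colSums(-fldI$ezz) * px - 3e-3)), 1e-6)
})

test_that("the Love-consistent phantom couples strain to the analytic stress field", {
  sp <- tinyPhantom(stressModel = "love", noiseSd = 0)
  fld <- phantomDisplacementField(sp, 3e-3)
  # strain decays with depth like the stress field
  n <- sp@imageSize[1]
  centre <- ceiling(n / 2)
  eps <- -fld$ezz[, centre]
  expect_gt(eps[10], eps[n %/% 2])
  # centre-column integral equals the applied compression (calibration)
  expect_lt(abs(sum(eps) * sp@geometry@pixelSize - 3e-3), 1e-12)
  # pointwise consistency: sigma / eps returns the body modulus
  sig <- fld$pressure *
    totalStressField(contactArea(sp@geometry), sp@geometry,
                     sp@imageSize)@sigmaZz
  epsFull <- -fld$ezz
  expect_equal(median(sig / epsFull), 6920, tolerance = 1e-6)
  # lateral expansion at the 2D ratio nu' = nu/(1+nu)
  expect_equal(median(fld$exx / (-fld$ezz)), 0.495 / 1.495, tolerance = 1e-9)
})

test_that("rendering is seed-stable with truth independent of the speckle seed", {
  spA <- tinyPhantom(seed = 1, n = 96L)
  spB <- tinyPhantom(seed = 2, n = 96L)
  dsA <- renderSequence(spA)
  dsA2 <- renderSequence(spA)
  dsB <- renderSequence(spB)
  expect_identical(dsA$cine@frames, dsA2$cine@frames)
  expect_false(identical(dsA$cine@frames, dsB$cine@frames))
  expect_identical(dsA$truth$ezz, dsB$truth$ezz)
  # zero compression with no noise: constant frames, zero forces
  sp0 <- tinyPhantom(noiseSd = 0, compressionDepth = 0, n = 96L)
  ds0 <- renderSequence(sp0)
  expect_equal(getFrame(ds0$cine, 1), getFrame(ds0$cine, nFrames(ds0$cine)))
  expect_equal(max(abs(ds0$forceLog@forces)), 0)
})

test_that("the non-linear force law follows the exponential stress-strain relation", {
  sp <- tinyPhantom(n = 96L, stressModel = "uniform", noiseSd = 0)
  sp@bodyMaterial <- elasticMaterial(18900, gamma = 10)
  ds <- renderSequence(sp)
  epsFinal <- 3e-3 / 25e-3
  expected <- 18900 * epsFinal * exp(3 * 10 * epsFinal^2)
  expect_equal(max(ds$truth$pressure), expected, tolerance = 1e-6)
  # and the linear case lacks the stiffening factor
  spLin <- tinyPhantom(bodyE = 18900, n = 96L, stressModel = "uniform")
  dsLin <- renderSequence(spLin)
  expect_equal(max(dsLin$truth$pressure), 18900 * epsFinal, tolerance = 1e-6)
})

test_that("phantom datasets round-trip through the disk format", {
  d <- withr::local_tempdir()
  sp <- tinyPhantom(n = 96L, seed = 6)
  ds <- renderSequence(sp)
  writePhantom(ds, d)
  cine <- readCine(file.path(d, "cine.tif"), pixelSize = sp@geometry@pixelSize,
                   frameRate = sp@frameRate)
  expect_equal(nFrames(cine), nFrames(ds$cine))
  expect_equal(getFrame(cine, 3), getFrame(ds$cine, 3), tolerance = 1e-4)
  lg <- readForceLog(file.path(d, "force.csv"))
  expect_equal(lg@forces, ds$forceLog@forces)
  Eback <- readMapTiff(file.path(d, "truth_E.tif"))
  expect_equal(Eback, ds$truth$EMap, tolerance = 1)
  meta <- jsonlite::read_json(file.path(d, "meta.json"))
  expect_equal(meta$body_E_Pa, 6920)
})
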