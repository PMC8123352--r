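test_that("preprocessing blur is the identity at sigma 0 and smooths speckle", {
  img <- makeSpeckle(c(64, 64), 0.15, 1.2, 5)
  expect_identical(preprocessFrame(img, 0), img)
  # impulse response: symmetric, mass-preserving, peaked at the impulse
  imp <- matrix(0, 31, 31); imp[16, 16] <- 1
  resp <- preprocessFrame(imp, 2)
  expect_equal(sum(resp), 1, tolerance = 1e-12)
  expect_equal(resp, t(resp), tolerance = 1e-12)
  expect_equal(which.max(resp), 16 + 15 * 31)
  expect_lt(var(as.vector(preprocessFrame(img, 1))), var(as.vector(img)))
})

test_that("frame correlation matches the 2D Pearson definition", {
  A <- makeSpeckle(c(80, 80), 0.15, 1.2, 6)
  expect_equal(frameCorrelation(A, A), 1)
  expect_equal(frameCorrelation(A, -A + 3), -1)
  # 10% noise: rho = 1/sqrt(1.01) analytically
  set.seed(8)
  reps <- replicate(20, {
    B <- A + rnorm(length(A), 0, 0.1 * sd(as.vector(A)))
    frameCorrelation(A, B)
  })
  expect_equal(mean(reps), 1 / sqrt(1.01), tolerance = 2e-3)
  # invariant to affine intensity rescaling of either argument
  B <- A + matrix(rnorm(length(A), 0, 0.05), nrow(A))
  expect_equal(frameCorrelation(2.3 * A + 0.7, B), frameCorrelation(A, B),
               tolerance = 1e-12)
  expect_error(frameCorrelation(A, matrix(1, 80, 80)), "zero-variance")
})

test_that("dense flow recovers zero, rigid and compressive motion", {
  pair <- shiftedSpecklePair(200, 3)
  ref <- preprocessFrame(pair$ref, 1)
  # identical frames give a near-zero field
  f0 <- estimateFlow(ref, ref)
  expect_lt(max(abs(f0@ux)), 0.05)
  expect_lt(max(abs(f0@uz)), 0.05)
  # rigid 3 px axial shift
  f <- estimateFlow(ref, preprocessFrame(pair$tgt, 1))
  expect_lt(abs(median(f@uz[30:170, 30:170]) - pair$trueUz), 0.2)
  expect_lt(abs(median(f@ux[30:170, 30:170])), 0.1)
  expect_error(estimateFlow(ref, ref, backend = "deepflow"),
               "lucaskanade, hornschunck")
})

test_that("analytic compression warp is tracked below 0.3 px endpoint error", {
  sp <- tinyPhantom(seed = 3, noiseSd = 0)
  ds <- renderSequence(sp)
  k <- nFrames(ds$cine)
  f <- estimateFlow(preprocessFrame(getFrame(ds$cine, 1), 1),
                    preprocessFrame(getFrame(ds$cine, k), 1))
  tr <- ds$truth
  inner <- 20:(nrow(f@uz) - 20)
  epe <- sqrt((f@ux[inner, inner] - tr$ux[inner, inner])^2 +
              (f@uz[inner, inner] - tr$uz[inner, inner])^2)
  expect_lt(median(epe), 0.3)
  # the Horn-Schunck fallback resolves a rigid shift as well
  pair <- shiftedSpecklePair(200, 3)
  fh <- estimateFlow(preprocessFrame(pair$ref, 1),
                     preprocessFrame(pair$tgt, 1), backend = "hornschunck")
  expect_lt(abs(median(fh@uz[30:170, 30:170]) - pair$trueUz), 0.3)
})

test_that("warping is exact for integer shifts and invertible for smooth fields", {
  img <- makeSpeckle(c(64, 64), 0.15, 1.5, 9)
  zero <- estimateFlow(img, img) # shape carrier
  zero@ux[] <- 0; zero@uz[] <- 0
  expect_equal(warpImage(img, zero), img)
  shift <- zero; shift@uz[] <- 2
  w <- warpImage(img, shift)
  expect_equal(w[1:62, ], img[3:64, ])
  expect_true(all(is.na(w[63:64, ])))
  # warp by u then by -u returns the original (PSNR > 35 dB) on a smooth image
  smooth <- preprocessFrame(img, 2)
  u <- zero
  u@ux <- matrix(1.5 * sin(seq(0, pi, length.out = 64)), 64, 64)
  u@uz <- matrix(rep(1.2 * cos(seq(0, pi, length.out = 64)), each = 64), 64)
  v <- u; v@ux <- -u@ux; v@uz <- -u@uz
  back <- warpImage(warpImage(smooth, u), v)
  ok <- !is.na(back)
  psnr <- 10 * log10(max(smooth)^2 / mean((back[ok] - smooth[ok])^2))
  expect_gt(psnr, 35)
})

test_that("sequence tracking switches references by correlation and composes fields", {
  sp <- tinyPhantom(seed = 4, noiseSd = 0.003)
  ds <- renderSequence(sp)
  # rhoMin = 0: no switch; rhoMin = 1: switch at every frame; both complete
  trNone <- trackSequence(ds$cine, rhoMin = 1e-9)
  expect_false(any(trNone$log$switched))
  trAll <- trackSequence(ds$cine, rhoMin = 1)
  expect_true(all(trAll$log$switched))
  # composed cumulative field agrees with the direct frame-1 -> k field
  k <- nFrames(ds$cine)
  direct <- trNone$fields[[k - 1]]
  composed <- trAll$fields[[k - 1]]
  inner <- 20:(nrow(direct@uz) - 20)
  expect_lt(median(abs(composed@uz[inner, inner] - direct@uz[inner, inner])),
            0.3)
  # a static noise-free sequence: rho = 1 everywhere, no switches, zero flow
  frames <- array(rep(makeSpeckle(c(64, 64), 0.15, 1.2, 2), 3), c(64, 64, 3))
  static <- cineSequence(frames, pixelSize = 1e-4, frameRate = 10)
  trS <- trackSequence(static)
  expect_true(all(trS$log$rho == 1))
  expect_false(any(trS$log$switched))
  expect_lt(max(abs(trS$fields[[2]]@uz)), 0.05)
})

test_that("an untrackable sequence aborts with a diagnostic", {
  set.seed(10)
  a <- makeSpeckle(c(64, 64), 0.15, 1.2, 2)
  b <- matrix(runif(64 * 64), 64)
  noisy <- cineSequence(array(c(a, b), c(64, 64, 2)), pixelSize = 1e-4,
                        frameRate = 10)
  expect_error(trackSequence(noisy), "untrackable")
})
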