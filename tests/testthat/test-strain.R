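test_that("Savitzky-Golay kernel has the closed form and zero sum", {
  k1 <- sgKernel(1, 1)
  expect_equal(k1, matrix(rep(c(-1 / 6, 0, 1 / 6), each = 3), 3))
  for (M in 1:4) {
    k <- sgKernel(M, 1)
    expect_equal(sum(k), 0)
    expect_equal(dim(k), c(2 * M + 1, 2 * M + 1))
    # odd symmetry along the derivative axis
    expect_equal(k, -k[, (2 * M + 1):1])
  }
  expect_error(sgKernel(0), "integer >= 1")
  # grid step scales the derivative: doubling GS halves the kernel
  expect_equal(sgKernel(2, 2), sgKernel(2, 1) / 2)
})

test_that("the derivative filter is exact on linear fields for M in 1..3", {
  n <- 24
  X <- matrix(rep(seq_len(n), each = n), n) # varies along columns (lateral)
  Z <- matrix(rep(seq_len(n), n), n)        # varies along rows (axial)
  for (M in 1:3) {
    dx <- strainComponent(0.37 * X, "x", M)
    expect_equal(median(dx, na.rm = TRUE), 0.37, tolerance = 1e-12)
    expect_lt(max(abs(dx - 0.37), na.rm = TRUE), 1e-10)
    # no variation along the other axis
    expect_lt(max(abs(strainComponent(0.37 * X, "z", M)), na.rm = TRUE), 1e-10)
    dz <- strainComponent(-0.21 * Z, "z", M)
    expect_lt(max(abs(dz + 0.21), na.rm = TRUE), 1e-10)
  }
  # constant field differentiates to zero
  expect_lt(max(abs(strainComponent(matrix(5, n, n), "x", 2)), na.rm = TRUE),
            1e-12)
  expect_error(strainComponent(matrix(1, 5, 5), "x", 5), "filter support")
})

test_that("row averaging cancels quadratic variation along the perpendicular axis", {
  n <- 30
  X <- matrix(rep(seq_len(n), each = n), n)
  Z <- matrix(rep(seq_len(n), n), n)
  u <- 0.4 * X + 0.02 * Z^2 # linear in x, quadratic in z
  dx <- strainComponent(u, "x", 3)
  expect_lt(max(abs(dx - 0.4), na.rm = TRUE), 1e-10)
})

test_that("rigid translations produce zero strain in all four components", {
  n <- 40
  ux <- matrix(2.5, n, n)
  uz <- matrix(-1.25, n, n)
  f <- new("DisplacementField", ux = ux, uz = uz, referenceIndex = 1L,
           targetIndex = 2L, cumulative = TRUE)
  s <- computeStrain(f, M = 5)
  for (comp in list(s@exx, s@exz, s@ezx, s@ezz))
    expect_lt(max(abs(comp[s@validMask])), 1e-12)
  # valid mask excludes the M-px border
  expect_false(any(s@validMask[1:5, ]))
  expect_false(any(s@validMask[, (n - 4):n]))
  expect_true(all(s@validMask[6:(n - 5), 6:(n - 5)]))
})

test_that("simulator strain is recovered within 10% RMS and incremental strains telescope", {
  sp <- tinyPhantom(seed = 5, noiseSd = 0.003)
  ds <- renderSequence(sp)
  tr <- trackSequence(ds$cine)
  strains <- strainSequence(tr$fields, "cumulative", M = 5)
  last <- strains[[length(strains)]]
  truth <- ds$truth$ezz
  m <- last@validMask
  m[1:20, ] <- FALSE; m[(nrow(m) - 20):nrow(m), ] <- FALSE
  rms <- sqrt(mean((last@ezz[m] - truth[m])^2)) / sqrt(mean(truth[m]^2))
  expect_lt(rms, 0.10)
  # incremental strains summed over frames approximate the cumulative strain
  inc <- strainSequence(tr$fields, "incremental", M = 5)
  total <- Reduce(`+`, lapply(inc, slot, "ezz"))
  expect_lt(median(abs(total[m] - last@ezz[m])) / median(abs(last@ezz[m])),
            0.10)
})

test_that("maps transport to the reference configuration and back", {
  img <- preprocessFrame(makeSpeckle(c(64, 64), 0.15, 1.5, 11), 2)
  f <- new("DisplacementField", ux = matrix(0, 64, 64),
           uz = matrix(3, 64, 64), referenceIndex = 1L, targetIndex = 2L,
           cumulative = TRUE)
  moved <- warpFieldToReference(img, f)
  expect_equal(moved[1:61, ], img[4:64, ])
  # zero field is the identity
  f0 <- f; f0@uz[] <- 0
  expect_equal(warpFieldToReference(img, f0), img)
})
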