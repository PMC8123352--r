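test_that("contact detection finds the first threshold crossing", {
  curve <- loadCurve(c(0, 1e-4, 2e-4, 3e-4), c(0, 0.05, 0.12, 0.3))
  expect_equal(detectContact(curve, 0.1), 3)
  expect_equal(detectContact(curve, 0), 1)
  zero <- loadCurve(c(0, 1e-4), c(0, 0))
  expect_error(detectContact(zero, 0.1), "never reaches")
})

test_that("the compression estimator round-trips the bonded-block model", {
  h <- 45e-3; A <- 625e-6; S <- 0.25
  curve <- simulateCompressionCurve(6920, h, A, S)
  expect_equal(compressionModulus(curve, h, A, S, contactThreshold = 0),
               6920, tolerance = 1e-3)
  # linear in the forces
  curve2 <- curve; curve2$force_n <- 2 * curve2$force_n
  expect_equal(compressionModulus(curve2, h, A, S, contactThreshold = 0),
               2 * 6920, tolerance = 1e-3)
  # rescaling displacement steps with model-consistent forces is invariant
  half <- simulateCompressionCurve(6920, h, A, S, nSteps = 40,
                                   stepWidth = 0.1e-3)
  expect_equal(compressionModulus(half, h, A, S, contactThreshold = 0),
               6920, tolerance = 1e-3)
  # tension points (lambda >= 1) are excluded; all excluded errors
  flat <- loadCurve(c(0, 1e-4), c(0.2, 0.2))
  expect_error(compressionModulus(flat, h, A, S, contactThreshold = 0.1,
                                  maxStrain = 1e-9), "no usable")
})

test_that("the indentation estimator inverts the BASh relation", {
  spec <- indenterSpec(304e-6, 1.016)
  curve <- simulateIndentationCurve(10e3, spec)
  E <- indentationModulus(curve, spec, nu = 0.495, contactThreshold = 0)
  expect_equal(E, 10e3 * (1 - 0.495^2), tolerance = 1e-12)
  # nu = 0 returns M3' itself
  expect_equal(indentationModulus(curve, spec, nu = 0, contactThreshold = 0),
               10e3, tolerance = 1e-12)
  # the shape factor enters linearly
  spec1 <- indenterSpec(304e-6, 1.0)
  E1 <- indentationModulus(curve, spec1, nu = 0.495, contactThreshold = 0)
  expect_equal(E1 / E, 1.016, tolerance = 1e-12)
  # a flat curve has no contact stiffness
  flat <- loadCurve(c(0, 1e-4, 2e-4), c(0.2, 0.2, 0.2))
  expect_error(indentationModulus(flat, spec, contactThreshold = 0.1),
               "non-positive")
})

test_that("both estimators stay unbiased below 1% under 1% force noise", {
  h <- 45e-3; A <- 625e-6; S <- 0.25
  spec <- indenterSpec(304e-6, 1.016)
  set.seed(17)
  maxFc <- max(simulateCompressionCurve(6920, h, A, S)$force_n)
  maxFi <- max(simulateIndentationCurve(10e3, spec)$force_n)
  comp <- replicate(1000, compressionModulus(
    simulateCompressionCurve(6920, h, A, S, noiseSd = 0.01 * maxFc),
    h, A, S, contactThreshold = 0))
  ind <- replicate(1000, indentationModulus(
    simulateIndentationCurve(10e3, spec, noiseSd = 0.01 * maxFi),
    spec, nu = 0.495, contactThreshold = 0))
  expect_lt(abs(mean(comp) - 6920) / 6920, 0.01)
  expect_lt(abs(mean(ind) - 10e3 * (1 - 0.495^2)) / (10e3 * (1 - 0.495^2)),
            0.01)
})

test_that("repeat summaries report median, spread and maximum relative difference", {
  s <- mechrefSummary(c(6.5e3, 6.9e3, 7.3e3))
  expect_equal(s$median_Pa, 6.9e3)
  expect_equal(s$max_rel_diff_pct, 100 * 400 / 6900, tolerance = 1e-10)
})
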