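# Shared fixtures: all synthetic, generated in code at test time.

# A reduced phantom for unit tests: small frames and a low frame rate so a
# full compression fits in a handful of frames. Not the study conditions
# (those live in the phantomSpec() defaults and are exercised by the
# acceptance tests).
tinyPhantom <- function(bodyE = 6920, inclusionE = NULL, n = 128L,
                        seed = 1L, noiseSd = 0.005, stressModel = "love",
                        frameRate = 10, compressionSpeed = 3e-3,
                        compressionDepth = 3e-3) {
  sp <- phantomSpec(
    bodyMaterial = elasticMaterial(bodyE),
    inclusionMaterial = if (is.null(inclusionE)) NULL
                        else elasticMaterial(inclusionE),
    preset = "fast", seed = seed, noiseSd = noiseSd,
    stressModel = stressModel, frameRate = frameRate,
    compressionSpeed = compressionSpeed,
    compressionDepth = compressionDepth)
  sp@imageSize <- c(n, n)
  sp@geometry@pixelSize <- 25e-3 / n
  fov <- n * sp@geometry@pixelSize
  sp@inclusionCentre <- c(fov / 2, fov / 2)
  methods::validObject(sp)
  sp
}

# speckle pair related by a known integer axial shift (true uz = -shift)
shiftedSpecklePair <- function(n = 200, shift = 3, seed = 7) {
  ref <- makeSpeckle(c(n, n), 0.15, 1.2, seed)
  tgt <- rbind(ref[(shift + 1):n, ], ref[n:(n - shift + 1), ])
  list(ref = ref, tgt = tgt, trueUz = -shift)
}
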