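test_that("phantom generation is bit-identical for a fixed seed", {
  s <- phantomSpec(shape = c(40, 40, 40), nAxons = 4, seed = 13)
  a <- generateAxonPhantom(s)
  b <- generateAxonPhantom(s)
  expect_identical(volumeData(a$volume), volumeData(b$volume))
  expect_identical(volumeData(a$mask), volumeData(b$mask))
  expect_identical(a$truth$perAxonLength, b$truth$perAxonLength)
  # per-axon substreams: adding axon n+1 leaves axons 1..n unchanged
  s5 <- phantomSpec(shape = c(40, 40, 40), nAxons = 5, seed = 13)
  c5 <- suppressWarnings(generateAxonPhantom(s5))
  expect_identical(c5$truth$perAxonLength[1:4], a$truth$perAxonLength)
})

test_that("a straight tube has exact centerline length and near-analytic volume", {
  ph <- make_capsule_tube(3, 100)
  expect_equal(ph$truth$trueTotalLength, 100)
  expect_equal(length(ph$truth$perAxonLength), 1L)
  # capsule closed form: pi r^2 L + 4/3 pi r^3
  analytic <- pi * 9 * 100 + 4 / 3 * pi * 27
  expect_lt(abs(ph$truth$trueVoxelCount / analytic - 1), 0.05)
  # ground-truth bookkeeping is self-consistent
  expect_equal(ph$truth$trueVolumeFraction,
               ph$truth$trueVoxelCount / prod(dim(volumeData(ph$mask))))
  expect_equal(ph$truth$trueLengthDensity,
               100 / prod(dim(volumeData(ph$mask))))
})

test_that("noiseless phantoms close the loop with the morphometry module", {
  ph <- generateAxonPhantom(phantomSpec(shape = c(64, 64, 64), nAxons = 10,
                                        radius = 3, noiseSd = 0, seed = 7))
  # segmentation of the noiseless probability volume recovers the mask
  seg <- segmentVolume(ph$volume, minVoxels = 1)
  expect_identical(volumeData(seg$mask), volumeData(ph$mask))
  res <- measureMorphometry(ph$mask)
  expect_identical(res@volumeFraction, ph$truth$trueVolumeFraction)
  expect_lt(abs(res@meanRadiusImage - 3), 1)
  expect_lt(abs(res@lengthDensityImage - ph$truth$trueLengthDensity) /
              ph$truth$trueLengthDensity, 0.10)
})

test_that("segmentation recall decreases with phantom noise", {
  recall <- vapply(c(0, 0.1, 0.2, 0.35), function(ns) {
    r <- numeric(0)
    for (seed in 1:3) {
      ph <- generateAxonPhantom(phantomSpec(shape = c(40, 40, 40),
                                            nAxons = 4, noiseSd = ns,
                                            seed = seed))
      got <- volumeData(segmentVolume(ph$volume, minVoxels = 1)$mask)
      r <- c(r, sum(got & volumeData(ph$mask)) / sum(volumeData(ph$mask)))
    }
    mean(r)
  }, numeric(1))
  expect_true(all(diff(recall) <= 0))
  expect_equal(recall[1], 1)
})

test_that("degenerate phantom requests behave sensibly", {
  ph <- generateAxonPhantom(phantomSpec(shape = c(24, 24, 24), nAxons = 0,
                                        noiseSd = 0, seed = 1))
  expect_equal(sum(volumeData(ph$mask)), 0)
  expect_true(all(volumeData(ph$volume) == 0.2))
  expect_equal(ph$truth$trueTotalLength, 0)
  expect_error(phantomSpec(radius = 0.5), "radius")
  expect_error(phantomSpec(backgroundLevel = 0.96), "backgroundLevel")
  expect_error(generateAxonPhantom(phantomSpec(shape = c(8, 8, 8),
                                               radius = 6, nAxons = 1)),
               "too large")
  # an over-packed volume reports placement failures as warnings
  w <- capture_warnings(
    generateAxonPhantom(phantomSpec(shape = c(24, 24, 24), nAxons = 40,
                                    radius = 4, seed = 2)))
  expect_true(any(grepl("could not place", w)))
})

test_that("expansion pairs honour the identity and transform contracts", {
  idp <- generateExpansionPair(textureSeed = 5, scale = 1, rotation = 0,
                               translation = c(0, 0), noiseSd = 0)
  expect_identical(volumeData(idp$pre), volumeData(idp$post))
  tr <- generateExpansionPair(textureSeed = 5, scale = 3, rotation = 15)
  expect_equal(tr$transform$scale, 3)
  expect_equal(tr$transform$rotation, 15)
  expect_identical(dim(volumeData(tr$post)),
                   as.integer(ceiling(dim(volumeData(tr$pre)) * 3)))
  expect_error(generateExpansionPair(scale = 0), "scale")
})
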