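test_that("thresholding uses a strict inequality", {
  u <- ProbabilityVolume(array(0.7, c(3, 3, 3)))
  expect_equal(sum(volumeData(thresholdVolume(u, 0.7))), 0)
  u <- ProbabilityVolume(array(0.71, c(3, 3, 3)))
  expect_true(all(volumeData(thresholdVolume(u, 0.7))))
  v <- ProbabilityVolume(array(c(0.2, 0.7, 0.9, 0.9, 0.2, 0.7), c(1, 2, 3)))
  m <- thresholdVolume(v, 0.7)
  expect_identical(which(volumeData(m)), which(volumeData(v) > 0.7))
  expect_equal(sum(volumeData(m)), 2)
  expect_error(thresholdVolume(v, 1.2), "threshold")
  expect_error(thresholdVolume(v, -0.1), "threshold")
})

test_that("component filter keeps components of exactly the cutoff size", {
  # four separated boxes: 300, 256, 255, 100 voxels
  a <- array(FALSE, c(24, 40, 24))
  a[1:10, 1:10, 1:3] <- TRUE       # 300
  a[1:8, 15:22, 1:4] <- TRUE       # 256
  a[1:5, 24:40, 18:20] <- TRUE     # 5*17*3 = 255
  a[15:19, 1:5, 10:13] <- TRUE     # 100
  m <- AxonMask(a)
  out <- removeSmallComponents(m, minVoxels = 256, connectivity = 26)
  expect_equal(out$report$nComponentsBefore, 4L)
  expect_equal(out$report$nComponentsAfter, 2L)
  expect_equal(out$report$removedVoxels, 255L + 100L)
  expect_equal(sum(volumeData(out$mask)), 300L + 256L)
  expect_equal(minComponentVoxels(out$mask), 256L)
  # empty mask
  out <- removeSmallComponents(AxonMask(array(FALSE, c(4, 4, 4))), 256)
  expect_equal(out$report$nComponentsBefore, 0L)
  expect_equal(sum(volumeData(out$mask)), 0)
  expect_error(labelComponents(m, connectivity = 4), "connectivity")
})

test_that("segment composes thresholding and filtering", {
  ph <- generateAxonPhantom(phantomSpec(shape = c(48, 48, 48), nAxons = 2,
                                        noiseSd = 0, seed = 5))
  seg <- segmentVolume(ph$volume)
  two <- removeSmallComponents(thresholdVolume(ph$volume, 0.7), 256, 26)
  expect_identical(volumeData(seg$mask), volumeData(two$mask))
  # defaults match the standard parameters
  cfg <- pipelineConfig()
  expect_equal(cfg$threshold, 0.7)
  expect_equal(cfg$minComponentVoxels, 256)
  expect_equal(cfg$connectivity, 26)
  # a tube survives, an added 50-voxel blob does not
  pv <- volumeData(ph$volume)
  pv[40:44, 40:44, 44:45] <- 0.9  # 50-voxel blob
  seg2 <- segmentVolume(ProbabilityVolume(pv))
  expect_identical(volumeData(seg2$mask), volumeData(seg$mask))
  # zero threshold acts on the whole strictly-positive foreground
  seg0 <- segmentVolume(ph$volume, threshold = 0, minVoxels = 1)
  expect_true(all(volumeData(seg0$mask)))
})

test_that("segmentation is idempotent and monotone", {
  ph <- generateAxonPhantom(phantomSpec(shape = c(40, 40, 40), nAxons = 3,
                                        noiseSd = 0, seed = 9))
  mask1 <- segmentVolume(ph$volume)$mask
  # cast mask back to 0/1 probabilities and re-segment at 0.5
  again <- segmentVolume(ProbabilityVolume(volumeData(mask1) * 1),
                         threshold = 0.5)$mask
  expect_identical(volumeData(again), volumeData(mask1))
  # monotone in threshold and in the size cutoff
  v <- random_prob_volume(c(12, 12, 12), seed = 3)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8),
                   function(t) sum(volumeData(thresholdVolume(v, t))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
  m <- thresholdVolume(v, 0.6)
  sizes <- vapply(c(1, 3, 9, 27),
                  function(k) sum(volumeData(
                    removeSmallComponents(m, k)$mask)), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("scan-order labelling matches a brute-force flood fill", {
  set.seed(77)
  for (rep in 1:12) {
    d <- sample(3:8, 3, replace = TRUE)
    arr <- array(runif(prod(d)) > runif(1, 0.3, 0.7), d)
    for (conn in c(6, 18, 26)) {
      lab <- labelComponents(AxonMask(arr), conn)
      oracle <- flood_fill_label(arr, conn)
      expect_true(same_partition(lab, oracle))
      expect_equal(attr(lab, "n_components"), max(oracle))
    }
  }
})
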