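test_that("max projection takes the per-pixel maximum over z", {
  one <- ProbabilityVolume(array(runif(25), c(1, 5, 5)))
  expect_equal(volumeData(maxProject(one)),
               matrix(volumeData(one)[1, , ], 5, 5))
  two <- array(0, c(2, 1, 1)); two[, 1, 1] <- c(3, 7) / 10
  expect_equal(volumeData(maxProject(two))[1, 1], 0.7)
  # seeded 5-plane stack against a brute-force pixel loop
  set.seed(8)
  arr <- array(runif(5 * 6 * 7), c(5, 6, 7))
  proj <- volumeData(maxProject(arr))
  for (y in 1:6) for (x in 1:7)
    expect_equal(proj[y, x], max(arr[, y, x]))
})

test_that("patch/matrix ratio is the ratio of ROI mean intensities", {
  img <- matrix(100, 30, 30)
  p <- matrix(0L, 30, 30); m <- matrix(0L, 30, 30)
  p[2:6, 2:6] <- 1L;  m[20:24, 2:6] <- 1L
  p[2:6, 20:24] <- 2L; m[20:24, 20:24] <- 2L
  # uniform image: every ratio 1
  r <- patchMatrixRatio(img, p, m)
  expect_equal(unname(r$perPairRatio), c(1, 1))
  # pair 1 at 150/100, pair 2 at 100/100 -> mean 1.25
  img[p == 1L] <- 150
  r <- patchMatrixRatio(img, p, m)
  expect_equal(unname(r$perPairRatio), c(1.5, 1.0))
  expect_equal(r$meanRatio, 1.25)
  # invariant under global intensity scaling
  r2 <- patchMatrixRatio(img * 37.5, p, m)
  expect_equal(r2$perPairRatio, r$perPairRatio)
  # swapping masks inverts each ratio exactly
  rs <- patchMatrixRatio(img, m, p)
  expect_equal(unname(rs$perPairRatio), 1 / unname(r$perPairRatio))
  # zero-mean matrix ROI is excluded with a warning
  img0 <- img; img0[m == 2L] <- 0
  expect_warning(rz <- patchMatrixRatio(img0, p, m), "excluded")
  expect_equal(rz$nExcluded, 1L)
  expect_equal(rz$nPairs, 1L)
  # overlapping ROIs are rejected
  bad <- m; bad[2:6, 2:6] <- 1L
  expect_error(patchMatrixRatio(img, p, bad), "disjoint")
})

test_that("generated compartment images reproduce the constructed ratio", {
  g <- generateCompartmentImage(shape = c(160, 160), nPatches = 3,
                                patchIntensity = 200, matrixIntensity = 100,
                                noiseSd = 0, seed = 2)
  r <- patchMatrixRatio(g$image, g$patchLabels, g$matrixLabels)
  expect_equal(r$meanRatio, g$trueRatio)
  expect_equal(g$trueRatio, 2)
  expect_true(all(unname(r$perPairRatio) == 2))
  # equal intensities give ratio 1
  g1 <- generateCompartmentImage(shape = c(160, 160), nPatches = 2,
                                 patchIntensity = 120, matrixIntensity = 120,
                                 noiseSd = 0, seed = 3)
  expect_equal(g1$trueRatio, 1)
  expect_equal(patchMatrixRatio(g1$image, g1$patchLabels,
                                g1$matrixLabels)$meanRatio, 1)
  # with noise the measured ratio stays near truth
  gn <- generateCompartmentImage(shape = c(160, 160), nPatches = 3,
                                 patchIntensity = 200, matrixIntensity = 100,
                                 noiseSd = 5, seed = 4)
  rn <- patchMatrixRatio(gn$image, gn$patchLabels, gn$matrixLabels)
  expect_lt(abs(rn$meanRatio / 2 - 1), 0.05)
})

test_that("patch area fraction is the union share of the region", {
  region <- matrix(TRUE, 25, 40)   # 1000 px
  expect_equal(patchAreaFraction(matrix(FALSE, 25, 40), region), 0)
  expect_equal(patchAreaFraction(region, region), 1)
  # two 100-px patches overlapping by 20 px -> union 180 of 1000
  p1 <- matrix(FALSE, 25, 40); p1[1:10, 1:10] <- TRUE
  p2 <- matrix(FALSE, 25, 40); p2[1:10, 9:18] <- TRUE
  expect_equal(patchAreaFraction(list(p1, p2), region), 180 / 1000)
  # monotone non-decreasing as patches are added
  expect_gte(patchAreaFraction(list(p1, p2), region),
             patchAreaFraction(list(p1), region))
  # patches outside the region are an error
  reg2 <- matrix(FALSE, 25, 40); reg2[1:5, 1:5] <- TRUE
  expect_error(patchAreaFraction(p1, reg2), "outside")
})
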