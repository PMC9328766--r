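test_that("volume fraction is the foreground voxel share", {
  a <- array(FALSE, c(64, 64, 100))
  expect_equal(volumeFraction(AxonMask(a)), 0)
  a[10:12, 10:12, 1:100] <- TRUE   # 3 x 3 x 100 solid bar
  expect_equal(volumeFraction(AxonMask(a)), 900 / 409600)
  expect_equal(volumeFraction(AxonMask(array(TRUE, c(4, 4, 4)))), 1)
  # spacing cancels
  expect_equal(volumeFraction(AxonMask(a, spacing = c(0.522, 0.33, 0.33))),
               900 / 409600)
})

test_that("skeletonization reduces bars to their centre lines", {
  # single voxel: one node, no edges
  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  sk <- skeletonize(AxonMask(a))
  expect_equal(nrow(skeletonNodes(sk)), 1L)
  expect_equal(nrow(skeletonEdges(sk)), 0L)
  expect_equal(skeletonLength(sk), 0)
  # solid 3x3x100 bar: ~100-voxel centre line, length 99 +- 3 um
  a <- array(FALSE, c(8, 8, 104)); a[3:5, 3:5, 3:102] <- TRUE
  m <- AxonMask(a)
  sk <- skeletonize(m)
  expect_lt(abs(skeletonLength(sk) - 99), 3)
  expect_equal(length(unique(componentIds(sk))), 1L)
  # skeleton is a subset of the mask foreground
  expect_true(all(a[skeletonNodes(sk)]))
  # two disjoint bars give two trees
  b <- array(FALSE, c(12, 12, 50))
  b[2:4, 2:4, 2:48] <- TRUE
  b[8:10, 8:10, 2:48] <- TRUE
  sk2 <- skeletonize(AxonMask(b))
  expect_equal(length(unique(componentIds(sk2))), 2L)
  # empty mask gives an empty graph
  sk0 <- skeletonize(AxonMask(array(FALSE, c(4, 4, 4))))
  expect_equal(nrow(skeletonNodes(sk0)), 0L)
})

test_that("thinning is idempotent", {
  ph <- generateAxonPhantom(phantomSpec(shape = c(40, 40, 40), nAxons = 4,
                                        seed = 21))
  sk <- skeletonize(ph$mask)
  skelArr <- array(FALSE, dim(volumeData(ph$mask)))
  skelArr[skeletonNodes(sk)] <- TRUE
  sk2 <- skeletonize(AxonMask(skelArr))
  expect_identical(skeletonNodes(sk2), skeletonNodes(sk))
})

test_that("length density divides armature length by image volume", {
  a <- array(FALSE, c(64, 64, 100))
  a[10, 10, 1:100] <- TRUE   # one straight 100-voxel line
  m <- AxonMask(a)
  sk <- skeletonize(m)
  expect_equal(skeletonLengthDensity(sk, m), 99 / 409600)
  # empty skeleton
  m0 <- AxonMask(array(FALSE, c(4, 4, 4)))
  expect_equal(skeletonLengthDensity(skeletonize(m0), m0), 0)
  # spacing enters both length and volume
  m2 <- AxonMask(a, spacing = c(1, 1, 2))
  sk2 <- skeletonize(m2)
  expect_equal(skeletonLengthDensity(sk2, m2), 99 * 2 / (409600 * 2))
  # doubling the tube count approximately doubles density
  one <- generateAxonPhantom(phantomSpec(shape = c(64, 64, 64), nAxons = 4,
                                         radius = 2, seed = 31))
  two <- generateAxonPhantom(phantomSpec(shape = c(64, 64, 64), nAxons = 8,
                                         radius = 2, seed = 31))
  r1 <- measureMorphometry(one$mask)
  r2 <- measureMorphometry(two$mask)
  truthRatio <- two$truth$trueTotalLength / one$truth$trueTotalLength
  expect_lt(abs(r2@lengthDensityImage / r1@lengthDensityImage - truthRatio) /
              truthRatio, 0.10)
})

test_that("EDT radius matches nearest-background arithmetic", {
  a <- array(FALSE, c(5, 5, 5)); a[3, 3, 3] <- TRUE
  m <- AxonMask(a)
  expect_equal(meanRadius(skeletonize(m), m), 1)
  # anisotropic spacing: nearest background is along the finest axis
  m2 <- AxonMask(a, spacing = c(0.5, 1, 1))
  expect_equal(meanRadius(skeletonize(m2), m2), 0.5)
  expect_equal(meanRadius(skeletonize(m2), m2, assumeIsotropic = TRUE), 1)
  # empty skeleton is a flagged zero
  m0 <- AxonMask(array(FALSE, c(3, 3, 3)))
  r0 <- meanRadius(skeletonize(m0), m0)
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "empty"))
})

test_that("EDT agrees with brute force on small anisotropic masks", {
  set.seed(6)
  spx <- c(0.522, 0.33, 0.33)
  arr <- array(runif(6 * 7 * 5) > 0.5, c(6, 7, 5))
  edt <- distanceTransform(AxonMask(arr, spacing = spx))
  fg <- which(arr, arr.ind = TRUE)
  bg <- which(!arr, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    diff <- sweep(bg, 2, fg[i, ])
    dd <- sqrt(rowSums(sweep(diff, 2, spx, "*")^2))
    expect_equal(edt[fg[i, , drop = FALSE]], min(dd))
  }
  expect_true(all(edt[!arr] == 0))
})

test_that("cylinders recover their radius from skeleton-sampled EDT", {
  for (r in c(2, 4, 6)) {
    m <- make_digital_cylinder(r, 40)
    sk <- skeletonize(m)
    edt <- distanceTransform(m)
    nd <- skeletonNodes(sk)
    interior <- nd[nd[, 1] > r + 2 & nd[, 1] < 40 - (r + 2), , drop = FALSE]
    expect_lt(abs(mean(edt[interior]) - r), 0.75)
  }
  # two tubes of radius 2 and 6 with equal lengths average near 4
  twor <- make_capsule_tube(2, 36)$mask
  sixr <- make_capsule_tube(6, 36)$mask
  big <- array(FALSE, c(52, 44, 44))
  big[seq_len(dim(volumeData(twor))[1]), 1:15, 1:15] <-
    volumeData(twor)[, 1:15, 1:15]
  big[seq_len(dim(volumeData(sixr))[1]), 22:44, 22:44] <-
    volumeData(sixr)[, 1:23, 1:23]
  mb <- AxonMask(big)
  expect_lt(abs(meanRadius(skeletonize(mb), mb) - 4), 0.75)
})

test_that("tissue-unit conversion follows the stated scaling rules", {
  res <- new("MorphometryResult", volumeFraction = 0.05,
             lengthDensityImage = 1e-3, meanRadiusImage = 8,
             nComponents = 2L, nSkeletonVoxels = 50L, expansionFactor = 1,
             lengthDensityTissue = 1e-3, meanRadiusTissue = 8, empty = FALSE)
  # f = 1 leaves everything unchanged
  r1 <- toTissueUnits(res, 1)
  expect_equal(r1@meanRadiusTissue, 8)
  expect_equal(r1@lengthDensityTissue, 1e-3)
  # measured radius 8 at f = 4 is 2 um of tissue
  r4 <- toTissueUnits(res, 4)
  expect_equal(r4@meanRadiusTissue, 2)
  expect_equal(r4@lengthDensityTissue, 1.6e-2)
  expect_equal(r4@volumeFraction, 0.05)
  # f then 1/f is the identity to machine precision (factors compose)
  back <- toTissueUnits(toTissueUnits(res, 4.255), 1 / 4.255)
  expect_equal(back@meanRadiusTissue, res@meanRadiusImage)
  expect_equal(back@lengthDensityTissue, res@lengthDensityImage)
  expect_identical(back@volumeFraction, res@volumeFraction)
  expect_error(toTissueUnits(res, 0), "positive")
  expect_error(toTissueUnits(res, -2), "positive")
})

test_that("morphometry is invariant to translation and near-invariant to axis permutation", {
  ph <- generateAxonPhantom(phantomSpec(shape = c(40, 40, 40), nAxons = 3,
                                        seed = 5))
  a <- volumeData(ph$mask)
  base <- array(FALSE, dim(a) + 8); base[1:40, 1:40, 1:40] <- a
  shif <- array(FALSE, dim(a) + 8); shif[5:44, 5:44, 5:44] <- a
  rb <- measureMorphometry(AxonMask(base))
  rs <- measureMorphometry(AxonMask(shif))
  expect_equal(rs@volumeFraction, rb@volumeFraction)
  expect_lt(abs(rs@lengthDensityImage / rb@lengthDensityImage - 1), 0.02)
  expect_lt(abs(rs@meanRadiusImage / rb@meanRadiusImage - 1), 0.02)
  # permuting (z, y, x) under isotropic spacing: the volume fraction is
  # exact; skeleton metrics shift slightly with the directional peel
  # order of the thinning
  ph2 <- generateAxonPhantom(phantomSpec(shape = c(64, 64, 64), nAxons = 8,
                                         seed = 11))
  a2 <- volumeData(ph2$mask)
  r0 <- measureMorphometry(ph2$mask)
  for (perm in list(c(2, 3, 1), c(3, 1, 2))) {
    rp <- measureMorphometry(AxonMask(aperm(a2, perm)))
    expect_identical(rp@volumeFraction, r0@volumeFraction)
    expect_lt(abs(rp@lengthDensityImage / r0@lengthDensityImage - 1), 0.03)
    expect_lt(abs(rp@meanRadiusImage / r0@meanRadiusImage - 1), 0.03)
  }
})

test_that("measure recovers phantom ground truth and flags empty masks", {
  ph <- generateAxonPhantom(phantomSpec(shape = c(64, 64, 64), nAxons = 20,
                                        radius = 3, seed = 7))
  res <- measureMorphometry(ph$mask, expansionFactor = 4.25)
  expect_identical(res@volumeFraction, ph$truth$trueVolumeFraction)
  expect_lt(abs(res@meanRadiusImage - 3), 1)
  expect_lt(abs(res@lengthDensityImage - ph$truth$trueLengthDensity) /
              ph$truth$trueLengthDensity, 0.10)
  expect_equal(res@nComponents, ph$truth$nAxonsPlaced)
  expect_equal(res@expansionFactor, 4.25)
  expect_equal(res@meanRadiusTissue, res@meanRadiusImage / 4.25)
  # empty mask
  r0 <- measureMorphometry(AxonMask(array(FALSE, c(6, 6, 6))))
  expect_true(r0@empty)
  expect_equal(r0@volumeFraction, 0)
  expect_equal(r0@meanRadiusImage, 0)
  expect_equal(r0@lengthDensityImage, 0)
})
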