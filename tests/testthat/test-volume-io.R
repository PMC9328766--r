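test_that("TIFF stacks round-trip through write and read for all depths", {
  d <- c(4, 6, 5)
  for (bits in c(8L, 16L, 32L)) {
    set.seed(bits)
    vals <- if (bits == 8L) sample(0:255, prod(d), TRUE) / 255
            else if (bits == 16L) sample(0:65535, prod(d), TRUE) / 65535
            else runif(prod(d))
    v <- ProbabilityVolume(array(vals, d), spacing = c(0.522, 0.33, 0.33))
    f <- tempfile(fileext = ".tif")
    writeVolume(v, f, bitsPerSample = bits)
    back <- readVolume(f, spacing = c(0.522, 0.33, 0.33))
    expect_equal(volumeData(back), volumeData(v), tolerance = 1e-7)
    expect_identical(spacing(back), c(0.522, 0.33, 0.33))
    unlink(f)
  }
})

test_that("integer samples rescale by the dtype maximum", {
  # all-255 8-bit page maps to 1.0
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(1, 4, 4), f, bits.per.sample = 8L)
  v <- readVolume(f, spacing = c(1, 1, 1))
  expect_true(all(volumeData(v) == 1))
  # 16-bit single pixel at half depth maps to 32768/65535
  m <- matrix(0, 4, 4)
  m[2, 3] <- 32768 / 65535
  tiff::writeTIFF(m, f, bits.per.sample = 16L)
  v <- readVolume(f, spacing = c(1, 1, 1))
  expect_equal(volumeData(v)[1, 2, 3], 32768 / 65535)
  # 3-page stack of zeros keeps shape (z, y, x) and values
  tiff::writeTIFF(list(matrix(0, 2, 3), matrix(0, 2, 3), matrix(0, 2, 3)),
                  f, bits.per.sample = 8L)
  v <- readVolume(f, spacing = c(1, 1, 1))
  expect_identical(dim(volumeData(v)), c(3L, 2L, 3L))
  expect_true(all(volumeData(v) == 0))
  unlink(f)
})

test_that("invalid volume inputs are rejected", {
  expect_error(readVolume(tempfile(), c(1, 1, 1)), "cannot read")
  f <- tempfile(fileext = ".tif")
  tiff::writeTIFF(matrix(0.5, 4, 4), f)
  expect_error(readVolume(f, spacing = c(0, 1, 1)), "spacing")
  expect_error(readVolume(f, spacing = c(1, 1)), "spacing")
  unlink(f)
  expect_error(ProbabilityVolume(array(1.5, c(1, 1, 1))), "0, 1")
  expect_error(ProbabilityVolume(array(0.5, c(2, 2)), c(1, 1, 1)), "3D")
})

test_that("result records round-trip with full precision in CSV and JSON", {
  set.seed(42)
  df <- data.frame(id = c("a", "b", "c"),
                   x = runif(3) * 1e-3,
                   y = rnorm(3) * 1e6,
                   n = c(1L, 2L, 3L),
                   ok = c(TRUE, FALSE, TRUE))
  for (fmt in c("csv", "json")) {
    f <- tempfile(fileext = paste0(".", fmt))
    writeResults(df, f, fmt)
    back <- readResults(f)
    expect_identical(back$x, df$x)
    expect_identical(back$y, df$y)
    expect_equal(back$n, df$n)
    expect_equal(back$ok, df$ok)
    unlink(f)
  }
})

test_that("writeResults handles schemas, S4 records and empty input", {
  res <- new("MorphometryResult", volumeFraction = 0.1,
             lengthDensityImage = 2e-3, meanRadiusImage = 3.2,
             nComponents = 4L, nSkeletonVoxels = 120L, expansionFactor = 4.25,
             lengthDensityTissue = 2e-3 * 4.25^2,
             meanRadiusTissue = 3.2 / 4.25, empty = FALSE)
  f <- tempfile(fileext = ".csv")
  writeResults(list(res, res), f)
  back <- readResults(f)
  expect_equal(nrow(back), 2L)
  expect_identical(back$meanRadiusImage, c(3.2, 3.2))
  # header-only CSV from a zero-row frame
  writeResults(as.data.frame(res)[0, ], f)
  expect_equal(nrow(readResults(f)), 0L)
  expect_named(readResults(f), names(as.data.frame(res)))
  unlink(f)
  expect_error(writeResults(list(res, data.frame(a = 1)), f), "schema")
  expect_error(writeResults(list(), f), "schema")
})

test_that("planar images round-trip through TIFF and PNG", {
  set.seed(15)
  m <- matrix(runif(30), 5, 6)
  # TIFF written at 16 bits, PNG at 8 bits: quantization bounds the error
  for (spec in list(list(ext = ".tif", tol = 1 / 65535),
                    list(ext = ".png", tol = 1 / 255))) {
    f <- tempfile(fileext = spec$ext)
    writePlanarImage(PlanarImage(m), f)
    back <- readPlanarImage(f)
    expect_lt(max(abs(volumeData(back) - m)), spec$tol)
    unlink(f)
  }
})
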