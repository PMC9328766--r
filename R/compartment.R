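## Patch (striosome) versus matrix fluorescence quantification on
## max-projected images. ROIs are consumed as integer-labelled mask
## images: patch label k pairs with matrix label k, mirroring the
## practice of drawing a patch ROI and moving a copy of it into the
## surrounding matrix. The per-pair statistic is the ratio of mean
## intensities (not the mean of pixel ratios).

#' Maximum-intensity projection along z
#'
#' @param volume a [ProbabilityVolume-class] (or any 3D array in
#'   (z, y, x) order).
#' @return A [PlanarImage-class] holding the per-pixel maximum over z.
#' @export
maxProject <- function(volume) {
  arr <- if (is(volume, "ProbabilityVolume")) volumeData(volume) else volume
  if (length(dim(arr)) != 3L) stop("volume must be a 3D array")
  d <- dim(arr)
  proj <- matrix(arr[1, , ], d[2], d[3])
  if (d[1] > 1)
    for (z in 2:d[1]) proj <- pmax(proj, matrix(arr[z, , ], d[2], d[3]))
  PlanarImage(proj)
}

#' Patch/matrix fluorescence intensity ratio
#'
#' For every ROI pair k, the ratio of the mean intensity inside the
#' patch mask to the mean intensity inside the paired matrix mask; the
#' summary is the arithmetic mean over pairs. Pairs whose matrix mean
#' is zero are excluded with a warning and counted in `nExcluded`.
#'
#' @param image a [PlanarImage-class] or numeric matrix.
#' @param patchLabels integer matrix; pixels of patch ROI k carry
#'   label k (0 = outside all ROIs). A logical matrix is treated as a
#'   single ROI.
#' @param matrixLabels integer matrix of the paired matrix ROIs, same
#'   labelling; must be disjoint from the patch ROIs.
#' @return A `CompartmentResult` list: `perPairRatio` (named by label),
#'   `meanRatio`, `nPairs`, `nExcluded`.
#' @examples
#' img <- matrix(100, 20, 20); img[1:5, 1:5] <- 200
#' p <- matrix(0L, 20, 20); p[1:5, 1:5] <- 1L
#' m <- matrix(0L, 20, 20); m[10:14, 10:14] <- 1L
#' patchMatrixRatio(img, p, m)$meanRatio  # 2
#' @export
patchMatrixRatio <- function(image, patchLabels, matrixLabels) {
  img <- if (is(image, "PlanarImage")) volumeData(image) else as.matrix(image)
  if (is.logical(patchLabels)) patchLabels <- patchLabels * 1L
  if (is.logical(matrixLabels)) matrixLabels <- matrixLabels * 1L
  if (!identical(dim(img), dim(patchLabels)) ||
      !identical(dim(img), dim(matrixLabels)))
    stop("image and ROI masks must share one shape")
  if (any(patchLabels > 0 & matrixLabels > 0))
    stop("patch and matrix ROIs must be disjoint")
  ids <- sort(intersect(unique(patchLabels[patchLabels > 0]),
                        unique(matrixLabels[matrixLabels > 0])))
  if (length(ids) == 0L) stop("no paired ROI labels found")
  ratios <- numeric(0)
  nExcluded <- 0L
  for (k in ids) {
    pm <- mean(img[patchLabels == k])
    mm <- mean(img[matrixLabels == k])
    if (!is.finite(mm) || mm == 0) {
      warning("matrix ROI ", k, " has zero mean intensity; pair excluded")
      nExcluded <- nExcluded + 1L
      next
    }
    ratios <- c(ratios, setNames(pm / mm, k))
  }
  if (length(ratios) == 0L) stop("all ROI pairs were excluded")
  structure(list(perPairRatio = ratios, meanRatio = mean(ratios),
                 nPairs = length(ratios), nExcluded = nExcluded),
            class = "CompartmentResult")
}

#' @export
print.CompartmentResult <- function(x, ...) {
  cat(sprintf("CompartmentResult: %d ROI pairs (%d excluded)\n",
              x$nPairs, x$nExcluded))
  cat(sprintf("  mean patch/matrix ratio: %.4f\n", x$meanRatio))
  invisible(x)
}

#' Fraction of a region covered by patches
#'
#' Union area of the patch masks divided by the region area.
#'
#' @param patchMasks a logical matrix, an integer label matrix (labels
#'   > 0 are patch pixels), or a list of logical matrices.
#' @param regionMask logical matrix delimiting the reference region;
#'   every patch pixel must lie inside it.
#' @return A dimensionless fraction in \[0, 1\].
#' @export
patchAreaFraction <- function(patchMasks, regionMask) {
  if (!is.list(patchMasks)) patchMasks <- list(patchMasks)
  u <- NULL
  for (p in patchMasks) {
    pm <- if (is.logical(p)) p else p > 0
    u <- if (is.null(u)) pm else u | pm
  }
  regionMask <- regionMask > 0
  if (!identical(dim(u), dim(regionMask)))
    stop("patch masks and region mask must share one shape")
  if (any(u & !regionMask))
    stop("patch pixels fall outside the region mask")
  sum(u) / sum(regionMask)
}
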