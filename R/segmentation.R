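## Probability map -> analysis-ready binary mask, in two stages:
## strict thresholding (voxel kept iff p > threshold) and removal of
## connected components smaller than a voxel-count cutoff ("smaller
## than" is strict: a component of exactly the cutoff size is kept).

#' Threshold a probability volume (strict inequality)
#'
#' A voxel enters the mask exactly when its probability is strictly
#' greater than `threshold`; a uniform volume at the threshold value
#' therefore produces an empty mask.
#'
#' @param volume a [ProbabilityVolume-class].
#' @param threshold probability cutoff in \[0, 1\] (default 0.7).
#' @return An [AxonMask-class] with `minComponentVoxels = 1`.
#' @examples
#' v <- ProbabilityVolume(array(c(0.2, 0.7, 0.9, 0.9), c(1, 2, 2)))
#' sum(volumeData(thresholdVolume(v, 0.7)))  # only the two 0.9 voxels
#' @export
thresholdVolume <- function(volume, threshold = 0.7) {
  stopifnot(is(volume, "ProbabilityVolume"))
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1]")
  AxonMask(volumeData(volume) > threshold, spacing = spacing(volume),
           thresholdUsed = threshold, minComponentVoxels = 1L)
}

#' Label connected components of a 3D mask
#'
#' Deterministic scan-order labelling (labels 1..k in order of first
#' encounter) under 6-, 18- or 26-connectivity.
#'
#' @param mask an [AxonMask-class] or 3D logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of the same shape; 0 marks background. The
#'   number of components is attached as attribute `n_components`.
#' @export
labelComponents <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be one of 6, 18, 26")
  arr <- if (is(mask, "AxonMask")) volumeData(mask) else mask
  d <- dim(arr)
  if (length(d) != 3L) stop("mask must be a 3D array")
  lab <- cc_label_cpp(as.logical(arr), as.integer(d), as.integer(connectivity))
  n <- attr(lab, "n_components")
  lab <- array(lab, d)
  attr(lab, "n_components") <- n
  lab
}

#' Remove small connected components from a mask
#'
#' Components with strictly fewer than `minVoxels` voxels are removed;
#' components of exactly `minVoxels` voxels are kept. Components
#' touching the volume border are treated like any other.
#'
#' @param mask an [AxonMask-class].
#' @param minVoxels minimum surviving component size in voxels
#'   (default 256).
#' @param connectivity 6, 18 or 26 (default 26; thin curvilinear axons
#'   traverse diagonal voxel steps, which 6-connectivity would fragment).
#' @return A list with elements `mask` (filtered [AxonMask-class]) and
#'   `report` (a `ComponentReport`: components before/after, voxels
#'   removed, and a component-size histogram).
#' @export
removeSmallComponents <- function(mask, minVoxels = 256, connectivity = 26) {
  stopifnot(is(mask, "AxonMask"))
  if (length(minVoxels) != 1L || minVoxels < 1)
    stop("minVoxels must be a single count >= 1")
  lab <- labelComponents(mask, connectivity)
  nBefore <- attr(lab, "n_components")
  sizes <- tabulate(lab, nbins = max(nBefore, 1L))
  if (nBefore == 0L) sizes <- integer(0)
  keep <- which(sizes >= minVoxels)
  removed <- sum(sizes[sizes < minVoxels])
  newdata <- array(lab %in% keep, dim(volumeData(mask)))
  hist <- table(sizes)
  report <- structure(
    list(nComponentsBefore = nBefore,
         nComponentsAfter = length(keep),
         removedVoxels = as.integer(removed),
         sizeHistogram = hist,
         minVoxels = minVoxels,
         connectivity = connectivity),
    class = "ComponentReport")
  out <- AxonMask(newdata, spacing = spacing(mask),
                  thresholdUsed = thresholdUsed(mask),
                  minComponentVoxels = as.integer(minVoxels))
  list(mask = out, report = report)
}

#' @export
print.ComponentReport <- function(x, ...) {
  cat(sprintf(
    "ComponentReport: %d -> %d components (connectivity %d, cutoff %g)\n",
    x$nComponentsBefore, x$nComponentsAfter, x$connectivity, x$minVoxels))
  cat(sprintf("  removed %d voxels in %d components\n", x$removedVoxels,
              x$nComponentsBefore - x$nComponentsAfter))
  invisible(x)
}

#' Segment a probability volume into an axon mask
#'
#' Composition of [thresholdVolume()] and [removeSmallComponents()]
#' with the standard defaults (threshold 0.7, cutoff 256 voxels,
#' 26-connectivity).
#'
#' @param volume a [ProbabilityVolume-class].
#' @param config optional [pipelineConfig()]; when given, its
#'   `threshold`, `minComponentVoxels` and `connectivity` override the
#'   other arguments.
#' @param threshold probability cutoff (default 0.7).
#' @param minVoxels minimum component size (default 256).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return A list with `mask` and `report`, as [removeSmallComponents()].
#' @examples
#' ph <- generateAxonPhantom(phantomSpec(shape = c(32, 32, 32), nAxons = 2,
#'                                       seed = 7))
#' seg <- segmentVolume(ph$volume)
#' seg$report
#' @export
segmentVolume <- function(volume, config = NULL, threshold = 0.7,
                          minVoxels = 256, connectivity = 26) {
  if (!is.null(config)) {
    threshold <- config$threshold
    minVoxels <- config$minComponentVoxels
    connectivity <- config$connectivity
  }
  m <- thresholdVolume(volume, threshold)
  removeSmallComponents(m, minVoxels = minVoxels, connectivity = connectivity)
}
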