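#' Construct a ProbabilityVolume
#'
#' @param data 3D numeric array in (z, y, x) order with values in \[0, 1\].
#' @param spacing numeric(3), voxel size in micrometres (z, y, x).
#' @param name free-text identifier.
#' @return A [ProbabilityVolume-class] object.
#' @examples
#' v <- ProbabilityVolume(array(runif(8), c(2, 2, 2)), spacing = c(1, 1, 1))
#' @export
ProbabilityVolume <- function(data, spacing = c(1, 1, 1), name = "") {
  new("ProbabilityVolume", data = data, spacing = as.numeric(spacing),
      name = name)
}

#' Construct an AxonMask
#'
#' @param data 3D logical array in (z, y, x) order.
#' @param spacing numeric(3), voxel size in micrometres (z, y, x).
#' @param thresholdUsed probability threshold recorded as provenance.
#' @param minComponentVoxels minimum component size enforced so far.
#' @return An [AxonMask-class] object.
#' @export
AxonMask <- function(data, spacing = c(1, 1, 1), thresholdUsed = NA_real_,
                     minComponentVoxels = 1L) {
  storage.mode(data) <- "logical"
  new("AxonMask", data = data, spacing = as.numeric(spacing),
      thresholdUsed = thresholdUsed,
      minComponentVoxels = as.integer(minComponentVoxels))
}

#' Construct a PlanarImage
#'
#' @param data numeric matrix (row = y, column = x).
#' @param pixelSize micrometres per pixel; `NA` when unknown.
#' @return A [PlanarImage-class] object.
#' @export
PlanarImage <- function(data, pixelSize = NA_real_) {
  new("PlanarImage", data = as.matrix(data), pixelSize = as.numeric(pixelSize))
}

#' @name accessors
#' @title Accessors for exmorph data objects
#' @description `volumeData()` returns the raw array/matrix of a volume,
#'   mask or planar image; `spacing()` the per-axis voxel size in
#'   micrometres; `thresholdUsed()` and `minComponentVoxels()` the
#'   segmentation provenance of an [AxonMask-class].
#' @param x an exmorph data object.
#' @return The slot value (array, numeric vector, or scalar).
NULL

#' @rdname accessors
#' @export
setGeneric("volumeData", function(x) standardGeneric("volumeData"))
#' @rdname accessors
#' @export
setMethod("volumeData", "ProbabilityVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volumeData", "AxonMask", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("volumeData", "PlanarImage", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))
#' @rdname accessors
#' @export
setMethod("spacing", "ProbabilityVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "AxonMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "SkeletonGraph", function(x) x@spacing)

#' @rdname accessors
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))
#' @rdname accessors
#' @export
setMethod("thresholdUsed", "AxonMask", function(x) x@thresholdUsed)

#' @rdname accessors
#' @export
setGeneric("minComponentVoxels",
           function(x) standardGeneric("minComponentVoxels"))
#' @rdname accessors
#' @export
setMethod("minComponentVoxels", "AxonMask", function(x) x@minComponentVoxels)

#' @name skeleton-accessors
#' @title Accessors for SkeletonGraph objects
#' @param x a [SkeletonGraph-class].
#' @return `skeletonNodes()`: integer matrix of voxel indices;
#'   `skeletonEdges()`: integer matrix of node index pairs;
#'   `skeletonWeights()`: numeric edge lengths (um); `skeletonLength()`:
#'   total forest edge length (um); `componentIds()`: integer label per
#'   node.
NULL

#' @rdname skeleton-accessors
#' @export
setGeneric("skeletonNodes", function(x) standardGeneric("skeletonNodes"))
#' @rdname skeleton-accessors
#' @export
setMethod("skeletonNodes", "SkeletonGraph", function(x) x@nodes)

#' @rdname skeleton-accessors
#' @export
setGeneric("skeletonEdges", function(x) standardGeneric("skeletonEdges"))
#' @rdname skeleton-accessors
#' @export
setMethod("skeletonEdges", "SkeletonGraph", function(x) x@edges)

#' @rdname skeleton-accessors
#' @export
setGeneric("skeletonWeights", function(x) standardGeneric("skeletonWeights"))
#' @rdname skeleton-accessors
#' @export
setMethod("skeletonWeights", "SkeletonGraph", function(x) x@weights)

#' @rdname skeleton-accessors
#' @param raw return the raw voxel step sum instead of the smoothed
#'   armature length.
#' @export
setGeneric("skeletonLength",
           function(x, raw = FALSE) standardGeneric("skeletonLength"))
#' @rdname skeleton-accessors
#' @export
setMethod("skeletonLength", "SkeletonGraph", function(x, raw = FALSE) {
  if (raw) sum(x@weights) else x@smoothedLength
})

#' @rdname skeleton-accessors
#' @export
setGeneric("componentIds", function(x) standardGeneric("componentIds"))
#' @rdname skeleton-accessors
#' @export
setMethod("componentIds", "SkeletonGraph", function(x) x@componentId)

#' @rdname accessors
#' @export
setGeneric("expansionScale", function(x) standardGeneric("expansionScale"))
#' @rdname accessors
#' @export
setMethod("expansionScale", "ExpansionEstimate", function(x) x@scale)

setMethod("show", "ProbabilityVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("ProbabilityVolume '%s': %d x %d x %d voxels (z, y, x)\n",
              object@name, d[1], d[2], d[3]))
  cat(sprintf("  spacing (um): %s\n",
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  value range: [%.4f, %.4f]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "AxonMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("AxonMask: %d x %d x %d voxels (z, y, x)\n", d[1], d[2], d[3]))
  cat(sprintf("  spacing (um): %s\n",
              paste(format(object@spacing), collapse = " x ")))
  cat(sprintf("  foreground: %d voxels (%.3f%%)\n", sum(object@data),
              100 * mean(object@data)))
  cat(sprintf("  threshold: %s; min component: %d voxels\n",
              format(object@thresholdUsed), object@minComponentVoxels))
})

setMethod("show", "PlanarImage", function(object) {
  cat(sprintf("PlanarImage: %d x %d pixels; pixel size: %s um\n",
              nrow(object@data), ncol(object@data),
              ifelse(is.na(object@pixelSize), "unknown",
                     format(object@pixelSize))))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d nodes, %d forest edges, %d components\n",
              nrow(object@nodes), nrow(object@edges),
              length(unique(object@componentId))))
  cat(sprintf("  armature length: %.3f um (raw step sum %.3f um)\n",
              object@smoothedLength, sum(object@weights)))
})

setMethod("show", "MorphometryResult", function(object) {
  cat("MorphometryResult\n")
  cat(sprintf("  volume fraction:        %.6g\n", object@volumeFraction))
  cat(sprintf("  length density (image): %.6g um/um^3\n",
              object@lengthDensityImage))
  cat(sprintf("  mean radius (image):    %.6g um\n", object@meanRadiusImage))
  cat(sprintf("  expansion factor:       %.4g\n", object@expansionFactor))
  cat(sprintf("  length density (tissue): %.6g um/um^3\n",
              object@lengthDensityTissue))
  cat(sprintf("  mean radius (tissue):    %.6g um\n", object@meanRadiusTissue))
  if (object@empty) cat("  [empty mask: metrics reported as 0]\n")
})

setMethod("show", "ExpansionEstimate", function(object) {
  cat(sprintf("ExpansionEstimate: scale %.4f, rotation %.2f deg\n",
              object@scale, object@rotation))
  cat(sprintf("  keypoints %d/%d, matches %d, inliers %d, rms %.3f px\n",
              object@nKeypointsPre, object@nKeypointsPost, object@nMatches,
              object@nInliers, object@rmsInlierResidual))
})

setMethod("show", "FractionatorDesign", function(object) {
  cat(sprintf(
    "FractionatorDesign: every %g sections, frame %g um^2, grid %g x %g um\n",
    object@sectionInterval, object@frameArea, object@gridStep[1],
    object@gridStep[2]))
  cat(sprintf("  dissector %g um in %g um sections (guard zone %g um)\n",
              object@dissectorHeight, object@meanSectionThickness,
              object@guardZone))
})

#' Coerce results to a one-row data.frame
#'
#' @param x a [MorphometryResult-class] or [ExpansionEstimate-class].
#' @param row.names,optional,... passed for S3 compatibility; ignored.
#' @return A one-row `data.frame` with one column per slot.
#' @export
as.data.frame.MorphometryResult <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(volumeFraction = x@volumeFraction,
             lengthDensityImage = x@lengthDensityImage,
             meanRadiusImage = x@meanRadiusImage,
             nComponents = x@nComponents,
             nSkeletonVoxels = x@nSkeletonVoxels,
             expansionFactor = x@expansionFactor,
             lengthDensityTissue = x@lengthDensityTissue,
             meanRadiusTissue = x@meanRadiusTissue,
             empty = x@empty)
}

#' @rdname as.data.frame.MorphometryResult
#' @export
as.data.frame.ExpansionEstimate <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  data.frame(scale = x@scale, rotation = x@rotation,
             translationY = x@translation[1], translationX = x@translation[2],
             nKeypointsPre = x@nKeypointsPre,
             nKeypointsPost = x@nKeypointsPost, nMatches = x@nMatches,
             nInliers = x@nInliers, rmsInlierResidual = x@rmsInlierResidual)
}

setAs("MorphometryResult", "data.frame",
      function(from) as.data.frame.MorphometryResult(from))
setAs("ExpansionEstimate", "data.frame",
      function(from) as.data.frame.ExpansionEstimate(from))
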