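## Central S4 data containers. Array axis order is fixed as (z, y, x):
## the first array dimension indexes TIFF pages (optical z), matching
## light-sheet stack convention. Spacing is per-axis voxel size in
## micrometres of post-expansion image space, in the same (z, y, x)
## order.

#' ProbabilityVolume: a 3D axon probability map
#'
#' Holds the per-voxel axon probability field produced by a 3D
#' segmentation network (or a synthetic stand-in), together with the
#' voxel spacing of the post-expansion image space. Values are
#' dimensionless probabilities in \[0, 1\].
#'
#' @slot data 3D numeric array, axis order (z, y, x), values in \[0, 1\].
#' @slot spacing numeric(3), per-axis voxel size in micrometres (z, y, x).
#' @slot name free-text identifier.
#'
#' @seealso [readVolume()], [thresholdVolume()], [generateAxonPhantom()]
#' @export
setClass("ProbabilityVolume",
  representation(data = "array", spacing = "numeric", name = "character"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1), name = ""))

setValidity("ProbabilityVolume", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (anyNA(d)) return("data must not contain NA")
  rng <- range(d)
  if (rng[1] < 0 || rng[2] > 1) return("all values must lie in [0, 1]")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (z, y, x)")
  TRUE
})

#' AxonMask: a binary axon segmentation
#'
#' A 3D boolean volume derived from a [ProbabilityVolume] by strict
#' thresholding and (optionally) small-component removal. Carries the
#' provenance needed to audit the segmentation: the threshold applied
#' and the minimum connected-component size retained.
#'
#' @slot data 3D logical array, axis order (z, y, x).
#' @slot spacing numeric(3), per-axis voxel size in micrometres (z, y, x).
#' @slot thresholdUsed probability threshold that produced the mask.
#' @slot minComponentVoxels minimum component size (voxels) enforced so far.
#'
#' @seealso [thresholdVolume()], [removeSmallComponents()], [measureMorphometry()]
#' @export
setClass("AxonMask",
  representation(data = "array", spacing = "numeric",
                 thresholdUsed = "numeric", minComponentVoxels = "integer"),
  prototype(data = array(FALSE, c(1, 1, 1)), spacing = c(1, 1, 1),
            thresholdUsed = NA_real_, minComponentVoxels = 1L))

setValidity("AxonMask", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3D array")
  if (!is.logical(d)) return("data must be logical")
  if (anyNA(d)) return("data must not contain NA")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values (z, y, x)")
  if (length(object@minComponentVoxels) != 1L || object@minComponentVoxels < 1L)
    return("minComponentVoxels must be a single count >= 1")
  TRUE
})

#' PlanarImage: a 2D grayscale image
#'
#' Carrier for pre-/post-expansion snapshots and max projections.
#' Intensities are in arbitrary units; `pixelSize` is in micrometres per
#' pixel, or `NA` when unknown.
#'
#' @slot data numeric matrix (row = y, column = x).
#' @slot pixelSize micrometres per pixel, `NA_real_` if unknown.
#'
#' @export
setClass("PlanarImage",
  representation(data = "matrix", pixelSize = "numeric"),
  prototype(data = matrix(0, 1, 1), pixelSize = NA_real_))

setValidity("PlanarImage", function(object) {
  if (!is.numeric(object@data)) return("data must be numeric")
  if (any(!is.finite(object@data))) return("data must be finite")
  if (length(object@pixelSize) != 1L) return("pixelSize must be length 1")
  TRUE
})

#' SkeletonGraph: the medial-axis armature of an axon mask
#'
#' Voxel-centred skeleton nodes plus the minimum spanning forest of
#' their 26-adjacency graph, with edges weighted by physical
#' centre-to-centre distance in micrometres. The forest is acyclic with
#' one tree per skeleton connected component; its total edge weight is
#' the skeleton (armature) length used for the length-density metric.
#'
#' Summing raw voxel-centre steps along a digital path overestimates
#' the length of oblique structures (lateral wobble of the thinned
#' line adds spurious diagonal steps), so the armature length is
#' measured on a lightly smoothed copy of the node positions (tree
#' Laplacian smoothing with endpoints and branch points anchored);
#' axis-aligned paths are unaffected. Both the raw step sum and the
#' smoothed length are kept.
#'
#' @slot nodes integer matrix (n x 3) of 1-based voxel indices (z, y, x).
#' @slot edges integer matrix (m x 2) of node indices.
#' @slot weights numeric(m), raw edge lengths in micrometres (voxel
#'   centre-to-centre steps).
#' @slot smoothedLength total armature length (um) after node smoothing.
#' @slot componentId integer(n), connected-component label per node.
#' @slot spacing numeric(3), voxel size (z, y, x) in micrometres.
#' @slot maskDim integer(3), shape of the source mask.
#'
#' @seealso [skeletonize()], [skeletonLength()], [skeletonLengthDensity()]
#' @export
setClass("SkeletonGraph",
  representation(nodes = "matrix", edges = "matrix", weights = "numeric",
                 smoothedLength = "numeric", componentId = "integer",
                 spacing = "numeric", maskDim = "integer"))

setValidity("SkeletonGraph", function(object) {
  if (ncol(object@nodes) != 3L && nrow(object@nodes) > 0)
    return("nodes must have 3 columns (z, y, x)")
  if (nrow(object@edges) != length(object@weights))
    return("one weight per edge required")
  if (nrow(object@nodes) != length(object@componentId))
    return("one componentId per node required")
  if (nrow(object@edges) > 0 &&
      (max(object@edges) > nrow(object@nodes) || min(object@edges) < 1))
    return("edge endpoints must index nodes")
  TRUE
})

#' MorphometryResult: the three axon metrics for one volume
#'
#' Axon volume fraction (dimensionless), skeleton length density (um of
#' armature per um^3 of image) and mean axon radius (um, the average
#' Euclidean distance transform value over skeleton voxels), reported in
#' both post-expansion image space and pre-expansion tissue space.
#' Tissue values divide lengths by the expansion factor f (so length
#' density scales by f^2, because the reference volume shrinks by f^3);
#' the volume fraction is a dimensionless ratio and does not change.
#'
#' @slot volumeFraction foreground voxels / total voxels, in \[0, 1\].
#' @slot lengthDensityImage um of skeleton per um^3 of image space.
#' @slot meanRadiusImage mean skeleton-sampled EDT radius, um (image space).
#' @slot nComponents number of connected components in the mask.
#' @slot nSkeletonVoxels number of skeleton voxels.
#' @slot expansionFactor linear expansion factor f used for tissue units.
#' @slot lengthDensityTissue lengthDensityImage * f^2.
#' @slot meanRadiusTissue meanRadiusImage / f.
#' @slot empty TRUE when the mask had no foreground (metrics reported as 0).
#'
#' @seealso [measureMorphometry()], [toTissueUnits()]
#' @export
setClass("MorphometryResult",
  representation(volumeFraction = "numeric", lengthDensityImage = "numeric",
                 meanRadiusImage = "numeric", nComponents = "integer",
                 nSkeletonVoxels = "integer", expansionFactor = "numeric",
                 lengthDensityTissue = "numeric", meanRadiusTissue = "numeric",
                 empty = "logical"))

setValidity("MorphometryResult", function(object) {
  if (object@volumeFraction < 0 || object@volumeFraction > 1)
    return("volumeFraction must lie in [0, 1]")
  if (object@meanRadiusImage < 0) return("meanRadiusImage must be >= 0")
  if (object@expansionFactor <= 0) return("expansionFactor must be > 0")
  TRUE
})

#' ExpansionEstimate: a recovered pre-to-post similarity transform
#'
#' The linear expansion factor (uniform scale), rotation and translation
#' recovered from a pre-/post-expansion image pair, together with the
#' keypoint, match and inlier counts needed to judge the fit.
#'
#' @slot scale linear expansion factor (> 0).
#' @slot rotation degrees, counter-clockwise.
#' @slot translation numeric(2), (dy, dx) in post-image pixels.
#' @slot nKeypointsPre,nKeypointsPost keypoints detected per image.
#' @slot nMatches ratio-test-passing descriptor matches.
#' @slot nInliers consensus inliers of the similarity fit.
#' @slot rmsInlierResidual root-mean-square inlier reprojection error, pixels.
#'
#' @seealso [estimateExpansion()], [summarizeFactors()]
#' @export
setClass("ExpansionEstimate",
  representation(scale = "numeric", rotation = "numeric",
                 translation = "numeric", nKeypointsPre = "integer",
                 nKeypointsPost = "integer", nMatches = "integer",
                 nInliers = "integer", rmsInlierResidual = "numeric"))

setValidity("ExpansionEstimate", function(object) {
  if (object@scale <= 0) return("scale must be > 0")
  if (object@nInliers > object@nMatches)
    return("inliers cannot exceed matches")
  if (object@nMatches > min(object@nKeypointsPre, object@nKeypointsPost))
    return("matches cannot exceed keypoints")
  TRUE
})

#' FractionatorDesign: optical fractionator sampling parameters
#'
#' The systematic sampling design of the optical fractionator: sections
#' kept every `sectionInterval` sections, a counting frame of
#' `frameArea` um^2 placed on a grid with step `gridStep` um, and an
#' optical dissector of height `dissectorHeight` um within sections of
#' measured mounted thickness `meanSectionThickness` um. The guard zone
#' (distance of the dissector from the section top) is recorded for
#' provenance but does not enter the estimator.
#'
#' @slot sectionInterval sections between sampled sections (inclusive step).
#' @slot frameArea counting frame area, um^2.
#' @slot gridStep numeric(2), (x, y) grid step, um.
#' @slot dissectorHeight optical dissector height, um.
#' @slot meanSectionThickness mean mounted section thickness, um.
#' @slot guardZone guard zone from section top, um (metadata only).
#'
#' @seealso [fractionatorDesign()], [estimateTotal()]
#' @export
setClass("FractionatorDesign",
  representation(sectionInterval = "numeric", frameArea = "numeric",
                 gridStep = "numeric", dissectorHeight = "numeric",
                 meanSectionThickness = "numeric", guardZone = "numeric"))

setValidity("FractionatorDesign", function(object) {
  v <- c(object@sectionInterval, object@frameArea, object@gridStep,
         object@dissectorHeight, object@meanSectionThickness)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all sampling parameters must be positive")
  if (length(object@gridStep) != 2L) return("gridStep must be (x, y)")
  if (object@dissectorHeight > object@meanSectionThickness)
    return("dissector height cannot exceed section thickness")
  if (object@frameArea > prod(object@gridStep))
    return("counting frame cannot exceed one grid tile")
  TRUE
})
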