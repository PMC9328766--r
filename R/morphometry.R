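## The three global axon metrics. All physical quantities honour the
## per-axis voxel spacing; `assumeIsotropic = TRUE` reproduces a
## spacing-blind variant (all axes treated as 1 um) for comparison with
## voxel-unit analyses.

#' Axon volume fraction
#'
#' Foreground voxels divided by total voxels. Spacing cancels, so the
#' fraction is identical in image and tissue space.
#'
#' @param mask an [AxonMask-class].
#' @return A dimensionless value in \[0, 1\].
#' @export
volumeFraction <- function(mask) {
  stopifnot(is(mask, "AxonMask"))
  mean(volumeData(mask))
}

#' Anisotropy-aware Euclidean distance transform
#'
#' For every foreground voxel, the exact Euclidean distance (um) to the
#' nearest background voxel centre, computed with per-axis spacing.
#'
#' @param mask an [AxonMask-class].
#' @param assumeIsotropic treat all axes as spacing 1 (voxel units).
#' @return Numeric array of distances (0 on background).
#' @export
distanceTransform <- function(mask, assumeIsotropic = FALSE) {
  stopifnot(is(mask, "AxonMask"))
  arr <- volumeData(mask)
  sp <- if (assumeIsotropic) c(1, 1, 1) else spacing(mask)
  array(edt3d_cpp(as.logical(arr), as.integer(dim(arr)), as.numeric(sp)),
        dim(arr))
}

#' Skeletonize a binary mask in 3D
#'
#' Deterministic topological thinning (6-subiteration directional
#' peeling with simple-point checks and endpoint preservation) reduces
#' the mask to a one-voxel-thick armature, without pruning of short
#' branches. The skeleton voxels are then joined into a minimum
#' spanning forest of their 26-adjacency graph, edges weighted by the
#' physical centre-to-centre distance; on a simple digital path the
#' forest reduces exactly to the chain of consecutive steps, while in
#' voxel cliques it avoids double-counting. The armature length carried
#' by the graph is measured on lightly smoothed node positions (see
#' [SkeletonGraph-class]), which removes the lateral wobble that makes
#' raw digital step sums overestimate oblique structures.
#'
#' @param mask an [AxonMask-class].
#' @param assumeIsotropic weight edges in voxel units instead of um.
#' @return A [SkeletonGraph-class]; empty mask gives an empty graph.
#' @seealso [skeletonLength()], [skeletonLengthDensity()], [meanRadius()]
#' @export
skeletonize <- function(mask, assumeIsotropic = FALSE) {
  stopifnot(is(mask, "AxonMask"))
  arr <- volumeData(mask)
  d <- dim(arr)
  sp <- if (assumeIsotropic) c(1, 1, 1) else spacing(mask)
  skel <- array(thin3d_cpp(as.logical(arr), as.integer(d)), d)
  nodes <- which(skel, arr.ind = TRUE)
  dimnames(nodes) <- NULL
  storage.mode(nodes) <- "integer"
  n <- nrow(nodes)
  if (n == 0L) {
    return(new("SkeletonGraph", nodes = nodes,
               edges = matrix(integer(0), 0, 2), weights = numeric(0),
               smoothedLength = 0, componentId = integer(0),
               spacing = as.numeric(sp), maskDim = as.integer(d)))
  }
  # 26-adjacency edges between skeleton voxels via linear-index hashing
  key <- (nodes[, 1] - 1) + as.numeric(d[1]) * (nodes[, 2] - 1) +
    as.numeric(d[1]) * d[2] * (nodes[, 3] - 1)
  ord <- order(key)
  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, , drop = FALSE]
  # half space: keep one of each +/- pair
  offsets <- offsets[offsets[, 1] > 0 |
                     (offsets[, 1] == 0 & offsets[, 2] > 0) |
                     (offsets[, 1] == 0 & offsets[, 2] == 0 &
                      offsets[, 3] > 0), , drop = FALSE]
  ea <- integer(0); eb <- integer(0); ew <- numeric(0)
  for (k in seq_len(nrow(offsets))) {
    o <- offsets[k, ]
    nb <- cbind(nodes[, 1] + o[1], nodes[, 2] + o[2], nodes[, 3] + o[3])
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    nkey <- (nb[ok, 1] - 1) + as.numeric(d[1]) * (nb[ok, 2] - 1) +
      as.numeric(d[1]) * d[2] * (nb[ok, 3] - 1)
    skey <- key[ord]
    fi <- findInterval(nkey, skey)
    hit <- fi >= 1
    hit[hit] <- skey[fi[hit]] == nkey[hit]
    if (!any(hit)) next
    ia <- which(ok)[hit]
    ib <- ord[fi[hit]]
    w <- sqrt(sum((o * sp)^2))
    ea <- c(ea, ia); eb <- c(eb, ib); ew <- c(ew, rep(w, length(ia)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ea) > 0) {
    g <- igraph::add_edges(g, rbind(ea, eb))
    igraph::E(g)$weight <- ew
  }
  forest <- igraph::mst(g)
  comp <- igraph::components(g)$membership
  fe <- igraph::as_edgelist(forest, names = FALSE)
  fw <- if (igraph::ecount(forest) > 0) igraph::E(forest)$weight else numeric(0)
  storage.mode(fe) <- "integer"
  new("SkeletonGraph", nodes = nodes, edges = fe, weights = as.numeric(fw),
      smoothedLength = smoothed_forest_length(nodes, fe, sp),
      componentId = as.integer(comp), spacing = as.numeric(sp),
      maskDim = as.integer(d))
}

# Armature length with sub-voxel de-aliasing: node positions are
# relaxed by tree Laplacian smoothing (endpoints and branch points
# anchored, path nodes moved toward their neighbour mean), then edge
# lengths are summed. Removes the lateral wobble of digital medial
# axes on oblique tubes while leaving axis-aligned paths unchanged.
smoothed_forest_length <- function(nodes, edges, sp, iters = 1,
                                   lambda = 0.45) {
  if (nrow(edges) == 0L) return(0)
  p <- t(t(nodes - 1) * sp)
  deg <- tabulate(as.vector(edges), nbins = nrow(nodes))
  anchored <- deg != 2L
  for (it in seq_len(iters)) {
    sx <- rowsum(rbind(p[edges[, 2], , drop = FALSE],
                       p[edges[, 1], , drop = FALSE]),
                 c(edges[, 1], edges[, 2]), reorder = FALSE)
    nb <- matrix(0, nrow(nodes), 3)
    nb[as.integer(rownames(sx)), ] <- sx
    pn <- (1 - lambda) * p + lambda * nb / pmax(deg, 1L)
    pn[anchored, ] <- p[anchored, ]
    p <- pn
  }
  sum(sqrt(rowSums((p[edges[, 1], , drop = FALSE] -
                    p[edges[, 2], , drop = FALSE])^2)))
}

#' Skeleton length density
#'
#' Total forest edge length of the skeleton divided by the physical
#' image volume (product of shape and spacing over all axes).
#'
#' @param skeleton a [SkeletonGraph-class] derived from `mask`.
#' @param mask the source [AxonMask-class].
#' @param assumeIsotropic use voxel units for the image volume.
#' @return Length density in um of skeleton per um^3 of image.
#' @export
skeletonLengthDensity <- function(skeleton, mask, assumeIsotropic = FALSE) {
  stopifnot(is(skeleton, "SkeletonGraph"), is(mask, "AxonMask"))
  d <- dim(volumeData(mask))
  if (!identical(as.integer(d), skeleton@maskDim))
    stop("skeleton was not derived from this mask (shape mismatch)")
  sp <- if (assumeIsotropic) c(1, 1, 1) else spacing(mask)
  skeletonLength(skeleton) / prod(d * sp)
}

#' Mean axon radius from the distance transform
#'
#' The Euclidean distance transform of the mask is evaluated at every
#' skeleton voxel (all components pooled) and averaged, unweighted. No
#' half-voxel correction is applied.
#'
#' @inheritParams skeletonLengthDensity
#' @return Mean radius in um. An empty skeleton yields 0 with attribute
#'   `empty = TRUE`.
#' @export
meanRadius <- function(skeleton, mask, assumeIsotropic = FALSE) {
  stopifnot(is(skeleton, "SkeletonGraph"), is(mask, "AxonMask"))
  d <- dim(volumeData(mask))
  if (!identical(as.integer(d), skeleton@maskDim))
    stop("skeleton was not derived from this mask (shape mismatch)")
  if (nrow(skeleton@nodes) == 0L)
    return(structure(0, empty = TRUE))
  edt <- distanceTransform(mask, assumeIsotropic = assumeIsotropic)
  mean(edt[skeleton@nodes])
}

#' Convert image-space morphometry to pre-expansion tissue units
#'
#' Lengths shrink by the linear expansion factor f, so the mean radius
#' divides by f; the reference volume shrinks by f^3, so length density
#' multiplies by f^2; the volume fraction is dimensionless and is
#' unchanged. Both image- and tissue-space values are kept on the
#' result so either convention can be audited. Successive applications
#' compose: the factors multiply, so applying f and then 1/f restores
#' the image-space values exactly.
#'
#' @param result a [MorphometryResult-class].
#' @param expansionFactor linear expansion factor f (> 0), multiplied
#'   into any factor already applied to `result`.
#' @return The result with `expansionFactor` and tissue-space fields set.
#' @export
toTissueUnits <- function(result, expansionFactor) {
  stopifnot(is(result, "MorphometryResult"))
  if (length(expansionFactor) != 1L || !is.finite(expansionFactor) ||
      expansionFactor <= 0)
    stop("expansionFactor must be a single positive value")
  f <- result@expansionFactor * expansionFactor
  result@expansionFactor <- f
  result@meanRadiusTissue <- result@meanRadiusImage / f
  result@lengthDensityTissue <- result@lengthDensityImage * f^2
  validObject(result)
  result
}

#' Measure all three axon metrics on a mask
#'
#' Orchestrates [volumeFraction()], [skeletonize()],
#' [skeletonLengthDensity()], [meanRadius()] and [toTissueUnits()].
#'
#' @param mask an [AxonMask-class].
#' @param expansionFactor linear expansion factor used for tissue units
#'   (default 1 = report image space twice).
#' @param assumeIsotropic compute in voxel units, ignoring spacing.
#' @return A [MorphometryResult-class].
#' @examples
#' ph <- generateAxonPhantom(phantomSpec(shape = c(32, 32, 32), nAxons = 2,
#'                                       seed = 7))
#' measureMorphometry(ph$mask, expansionFactor = 4.25)
#' @export
measureMorphometry <- function(mask, expansionFactor = 1,
                               assumeIsotropic = FALSE) {
  stopifnot(is(mask, "AxonMask"))
  vf <- volumeFraction(mask)
  sk <- skeletonize(mask, assumeIsotropic = assumeIsotropic)
  empty <- nrow(sk@nodes) == 0L
  ld <- skeletonLengthDensity(sk, mask, assumeIsotropic = assumeIsotropic)
  mr <- as.numeric(meanRadius(sk, mask, assumeIsotropic = assumeIsotropic))
  ncomp <- if (empty) 0L else length(unique(sk@componentId))
  res <- new("MorphometryResult", volumeFraction = vf,
             lengthDensityImage = ld, meanRadiusImage = mr,
             nComponents = ncomp, nSkeletonVoxels = nrow(sk@nodes),
             expansionFactor = 1, lengthDensityTissue = ld,
             meanRadiusTissue = mr, empty = empty)
  toTissueUnits(res, expansionFactor)
}
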