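## Synthetic ground-truth generators. Tubular axon phantoms emulate
## confident CNN probability maps over curvilinear structures:
## centerlines are persistent random walks rasterized at a fixed
## radius, rendered at foreground probability 0.95 over a configurable
## background, so the standard 0.7 threshold cleanly separates signal.
## Per-axon random substreams are derived from the master seed, so
## adding axon n+1 leaves axons 1..n unchanged.

FOREGROUND_P <- 0.95

derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (v in ix) s <- (s * 48271 + v) %% 2147483647
  as.integer(s)
}

#' Specification for a tubular axon phantom
#'
#' @param shape integer(3), volume shape (z, y, x) voxels (default 64^3,
#'   the working cube size of the segmentation network these phantoms
#'   emulate).
#' @param spacing numeric(3), voxel size in um (default isotropic 1).
#' @param nAxons number of tubes (default 10).
#' @param radius tube radius in voxels: a scalar, or a length-2 range
#'   sampled uniformly per axon (default 3).
#' @param tortuosity step-direction perturbation strength in \[0, 1\];
#'   0 gives straight tubes (default 0.3).
#' @param noiseSd Gaussian noise sd added to the probability field
#'   (default 0.05).
#' @param backgroundLevel background probability, must be below the
#'   foreground level 0.95 (default 0.2).
#' @param length optional fixed centerline length in um; by default each
#'   walk runs until it leaves the volume margin.
#' @param start optional fixed start point (z, y, x) in um; default random.
#' @param direction optional fixed initial direction (z, y, x); default
#'   random. Useful with `tortuosity = 0` for axis-aligned oracles.
#' @param seed master seed (default 1).
#' @return A `PhantomSpec` list.
#' @seealso [generateAxonPhantom()]
#' @export
phantomSpec <- function(shape = c(64, 64, 64), spacing = c(1, 1, 1),
                        nAxons = 10, radius = 3, tortuosity = 0.3,
                        noiseSd = 0.05, backgroundLevel = 0.2,
                        length = NULL, start = NULL, direction = NULL,
                        seed = 1) {
  if (any(radius < 1)) stop("radius must be >= 1 voxel")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (backgroundLevel < 0 || backgroundLevel >= FOREGROUND_P)
    stop("backgroundLevel must be in [0, ", FOREGROUND_P, ")")
  if (tortuosity < 0 || tortuosity > 1)
    stop("tortuosity must be in [0, 1]")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 nAxons = as.integer(nAxons), radius = radius,
                 tortuosity = tortuosity, noiseSd = noiseSd,
                 backgroundLevel = backgroundLevel, length = length,
                 start = start, direction = direction,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Named phantom presets
#'
#' `"default"` (10 tubes, radius 3), `"sparse"` (5 tubes), `"dense"`
#' (30 tubes), `"raptor-like"` (lower density, smaller radius, as in a
#' hypotrophic-axon condition) and `"wild-type-like"` (denser, radius 3).
#'
#' @param preset preset name.
#' @param seed master seed.
#' @return A `PhantomSpec`.
#' @export
phantomPreset <- function(preset = c("default", "sparse", "dense",
                                     "raptor-like", "wild-type-like"),
                          seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    "default" = phantomSpec(seed = seed),
    "sparse" = phantomSpec(nAxons = 5, seed = seed),
    "dense" = phantomSpec(nAxons = 30, seed = seed),
    "raptor-like" = phantomSpec(nAxons = 6, radius = 2, seed = seed),
    "wild-type-like" = phantomSpec(nAxons = 20, radius = 3, seed = seed))
}

random_unit3 <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

walk_centerline <- function(spec, radiusUm) {
  ext <- (spec$shape - 1) * spec$spacing     # physical extent, voxel centres
  margin <- radiusUm + min(spec$spacing)
  if (any(ext <= 2 * margin)) stop("radius too large for volume shape")
  if (is.null(spec$start)) {
    # start on a face of the interior margin box, heading inward, so
    # tubes span the volume instead of stubbing out near their origin
    face <- sample.int(3L, 1L)
    side <- sample(c(0L, 1L), 1L)
    start <- runif(3, margin, ext - margin)
    start[face] <- if (side == 0L) margin else ext[face] - margin
    dir <- random_unit3()
    inward <- if (side == 0L) 1 else -1
    dir[face] <- inward * abs(dir[face])
    if (abs(dir[face]) < 0.3) dir[face] <- inward * 0.3
    dir <- dir / sqrt(sum(dir^2))
  } else {
    start <- as.numeric(spec$start)
    dir <- if (is.null(spec$direction)) random_unit3()
           else spec$direction / sqrt(sum(spec$direction^2))
  }
  h <- min(spec$spacing)                      # step length, um
  maxSteps <- if (is.null(spec$length)) ceiling(3 * max(ext) / h)
              else ceiling(spec$length / h) + 1
  pts <- matrix(0, maxSteps + 1, 3)
  pts[1, ] <- start
  total <- 0
  n <- 1
  for (i in seq_len(maxSteps)) {
    step <- h
    if (!is.null(spec$length) && total + h > spec$length)
      step <- spec$length - total
    if (step <= 0) break
    nxt <- pts[n, ] + dir * step
    if (any(nxt < margin) || any(nxt > ext - margin)) break
    n <- n + 1
    pts[n, ] <- nxt
    total <- total + step
    if (!is.null(spec$length) && total >= spec$length) break
    if (spec$tortuosity > 0)
      dir <- dir + spec$tortuosity * 0.35 * rnorm(3)
    nrm <- sqrt(sum(dir^2))
    if (nrm < 1e-8) dir <- random_unit3() else dir <- dir / nrm
  }
  list(points = pts[seq_len(n), , drop = FALSE], length = total)
}

#' Generate a tubular axon phantom with exact ground truth
#'
#' Centerlines are persistent random walks (tortuosity 0 = straight);
#' each is rasterized by marking all voxels whose centre projects onto
#' the polyline within the tube radius. The probability volume renders
#' foreground at 0.95 and background at `spec$backgroundLevel`, plus
#' optional Gaussian noise clipped to \[0, 1\]. Tube overlap is
#' prevented by rejection sampling (up to 100 retries per axon, with a
#' one-voxel separation guard); failures to place an axon are reported
#' by warning, never silently. Outputs are bit-identical for a fixed
#' spec and seed.
#'
#' @param spec a [phantomSpec()].
#' @return A list: `volume` ([ProbabilityVolume-class]), `mask`
#'   (noiseless [AxonMask-class]), and `truth` (a `PhantomGroundTruth`
#'   list: per-axon centerlines, lengths and radii, the foreground voxel
#'   count, true volume fraction and true length density).
#' @examples
#' ph <- generateAxonPhantom(phantomSpec(shape = c(32, 32, 32), nAxons = 3,
#'                                       seed = 7))
#' ph$truth$trueVolumeFraction
#' @export
generateAxonPhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$shape
  acc <- array(FALSE, d)
  centerlines <- list()
  lengths <- numeric(0)
  radii <- numeric(0)
  nPlaced <- 0L
  for (a in seq_len(spec$nAxons)) {
    placed <- FALSE
    for (try in seq_len(100L)) {
      with_seed(derive_seed(spec$seed, a, try), {
        radiusVox <- if (length(spec$radius) == 2L)
          runif(1, spec$radius[1], spec$radius[2]) else spec$radius[1]
        radiusUm <- radiusVox * min(spec$spacing)
        cl <- walk_centerline(spec, radiusUm)
      })
      # reject stubs whose length is not large against their radius
      # (a squat capsule has no line-like medial axis to recover)
      if (is.null(spec$length) &&
          cl$length < max(10 * min(spec$spacing), 4 * radiusUm)) next
      tube <- array(rasterize_tube_cpp(cl$points, radiusUm, d,
                                       spec$spacing), d)
      # separation guard covers the diagonal voxel step, so distinct
      # tubes can never become 26-connected
      guard <- array(rasterize_tube_cpp(cl$points,
                                        radiusUm +
                                          sqrt(sum(spec$spacing^2)), d,
                                        spec$spacing), d)
      if (any(guard & acc)) next
      acc <- acc | tube
      centerlines[[length(centerlines) + 1L]] <- cl$points
      lengths <- c(lengths, cl$length)
      radii <- c(radii, radiusUm)
      nPlaced <- nPlaced + 1L
      placed <- TRUE
      break
    }
    if (!placed)
      warning("could not place axon ", a, " without overlap after 100 tries")
  }
  prob <- ifelse(acc, FOREGROUND_P, spec$backgroundLevel)
  if (spec$noiseSd > 0) {
    with_seed(derive_seed(spec$seed, 999983L), {
      prob <- prob + rnorm(length(prob), sd = spec$noiseSd)
    })
    prob <- array(pmin(pmax(prob, 0), 1), d)
  } else {
    prob <- array(prob, d)
  }
  physVol <- prod(d * spec$spacing)
  truth <- structure(list(
    centerlines = centerlines,
    perAxonLength = lengths,
    perAxonRadius = radii,
    nAxonsRequested = spec$nAxons,
    nAxonsPlaced = nPlaced,
    trueTotalLength = sum(lengths),
    trueVoxelCount = sum(acc),
    trueVolumeFraction = sum(acc) / prod(d),
    trueLengthDensity = sum(lengths) / physVol),
    class = "PhantomGroundTruth")
  list(volume = ProbabilityVolume(prob, spacing = spec$spacing,
                                  name = sprintf("phantom-seed%d", spec$seed)),
       mask = AxonMask(acc, spacing = spec$spacing, thresholdUsed = NA_real_,
                       minComponentVoxels = 1L),
       truth = truth)
}

#' Generate a pre-/post-expansion image pair with a known transform
#'
#' The pre image is a seeded field of Gaussian blobs (an analytic
#' texture). The post image is the same analytic field evaluated under
#' the exact similarity transform `x' = s R (x - c) + s c + t` (rotation
#' about the image centre), so resampling is exact to machine precision;
#' optional Gaussian pixel noise is then added to the post image.
#'
#' @param textureSeed seed for the blob texture.
#' @param scale linear scale factor s (> 0); the realistic default 4.25
#'   matches typical protein-retention expansion factors.
#' @param rotation degrees, counter-clockwise.
#' @param translation numeric(2), (dy, dx) extra shift in post pixels.
#' @param noiseSd Gaussian noise sd on the post image (intensities are
#'   in \[0, 1\]).
#' @param preSize integer(2), pre-image size in pixels (default 128^2).
#' @param nBlobs number of texture blobs (default 120).
#' @return A list: `pre`, `post` ([PlanarImage-class]) and `transform`
#'   (`scale`, `rotation`, `translation` = the effective (dy, dx) of the
#'   full mapping).
#' @export
generateExpansionPair <- function(textureSeed = 0, scale = 4.25,
                                  rotation = 0, translation = c(0, 0),
                                  noiseSd = 0, preSize = c(128, 128),
                                  nBlobs = 120) {
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a single positive value")
  with_seed(derive_seed(textureSeed, 7L), {
    cx <- runif(nBlobs, 6, preSize[2] - 7)   # 0-based col
    cy <- runif(nBlobs, 6, preSize[1] - 7)   # 0-based row
    sg <- runif(nBlobs, 1.8, 6)
    am <- runif(nBlobs, 0.3, 1)
  })
  render <- function(nr, nc, bx, by, bs, ba) {
    img <- matrix(0, nr, nc)
    for (b in seq_along(bx)) {
      ext <- ceiling(4 * bs[b])
      r0 <- max(0, floor(by[b]) - ext); r1 <- min(nr - 1, ceiling(by[b]) + ext)
      c0 <- max(0, floor(bx[b]) - ext); c1 <- min(nc - 1, ceiling(bx[b]) + ext)
      if (r0 > r1 || c0 > c1) next
      rr <- r0:r1; cc <- c0:c1
      g <- ba[b] * outer(exp(-(rr - by[b])^2 / (2 * bs[b]^2)),
                         exp(-(cc - bx[b])^2 / (2 * bs[b]^2)))
      img[rr + 1, cc + 1] <- img[rr + 1, cc + 1] + g
    }
    img / max(1, max(img))
  }
  pre <- render(preSize[1], preSize[2], cx, cy, sg, am)
  th <- rotation * pi / 180
  cpre <- c((preSize[2] - 1) / 2, (preSize[1] - 1) / 2)  # (x, y)
  postSize <- as.integer(ceiling(preSize * scale))
  # blob centres mapped into the post frame; rotation about the centre
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                             y = sin(th) * x + cos(th) * y)
  rc <- rot(cx - cpre[1], cy - cpre[2])
  pxc <- scale * rc$x + scale * cpre[1] + translation[2]
  pyc <- scale * rc$y + scale * cpre[2] + translation[1]
  post <- render(postSize[1], postSize[2], pxc, pyc, sg * scale, am)
  if (noiseSd > 0) {
    with_seed(derive_seed(textureSeed, 11L), {
      post <- post + rnorm(length(post), sd = noiseSd)
    })
    post <- matrix(pmin(pmax(post, 0), 1), postSize[1], postSize[2])
  }
  # effective translation of x' = sRx + t_eff
  teff <- c(scale * cpre[2] + translation[1] -
              scale * (sin(th) * cpre[1] + cos(th) * cpre[2]),
            scale * cpre[1] + translation[2] -
              scale * (cos(th) * cpre[1] - sin(th) * cpre[2]))
  list(pre = PlanarImage(pre), post = PlanarImage(post),
       transform = list(scale = scale, rotation = rotation,
                        translation = teff))
}

#' Generate a two-compartment (patch/matrix) striatal image
#'
#' Elliptical non-overlapping patches at `patchIntensity` on a
#' `matrixIntensity` background, with paired matrix ROIs (the same
#' ellipse translated outside all patches). The constructed intensity
#' ratio is `patchIntensity / matrixIntensity`.
#'
#' @param shape integer(2), image size (y, x) (default 256^2).
#' @param nPatches number of patches (default 5).
#' @param patchIntensity,matrixIntensity mean intensities, a.u.
#' @param noiseSd Gaussian pixel noise sd, a.u. (default 0).
#' @param seed master seed (default 1).
#' @return A list: `image` ([PlanarImage-class]), `patchLabels`,
#'   `matrixLabels` (integer matrices, label k pairs patch k with its
#'   matrix ROI), `trueRatio`.
#' @export
generateCompartmentImage <- function(shape = c(256, 256), nPatches = 5,
                                     patchIntensity = 200,
                                     matrixIntensity = 100, noiseSd = 0,
                                     seed = 1) {
  if (patchIntensity < 0 || matrixIntensity <= 0)
    stop("intensities must be non-negative (matrix strictly positive)")
  nr <- shape[1]; nc <- shape[2]
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ellipse <- function(cy, cx, a, b, ang) {
    dx <- colg - cx; dy <- rowg - cy
    xr <- cos(ang) * dx + sin(ang) * dy
    yr <- -sin(ang) * dx + cos(ang) * dy
    (xr / a)^2 + (yr / b)^2 <= 1
  }
  patchLab <- matrix(0L, nr, nc)
  matrixLab <- matrix(0L, nr, nc)
  with_seed(derive_seed(seed, 13L), {
    placedShapes <- list()
    k <- 0L
    axmin <- 0.05 * min(nr, nc)   # patch semi-axes scale with the image
    axmax <- 0.09 * min(nr, nc)
    for (p in seq_len(nPatches)) {
      done <- FALSE
      for (try in seq_len(200L)) {
        a <- runif(1, axmin, axmax); b <- runif(1, axmin, axmax)
        ang <- runif(1, 0, pi)
        cy <- runif(1, a + b + 2, nr - a - b - 2)
        cx <- runif(1, a + b + 2, nc - a - b - 2)
        # margin test against existing patches and matrix ROIs
        em <- ellipse(cy, cx, a + 4, b + 4, ang)
        if (any(em & (patchLab > 0 | matrixLab > 0))) next
        k <- k + 1L
        patchLab[ellipse(cy, cx, a, b, ang)] <- k
        placedShapes[[k]] <- list(a = a, b = b, ang = ang)
        done <- TRUE
        break
      }
      if (!done) stop("cannot place ", nPatches, " non-overlapping patches ",
                      "in a ", nr, " x ", nc, " image")
    }
    # paired matrix ROIs: same shape, translated clear of all patches
    for (j in seq_len(k)) {
      s <- placedShapes[[j]]
      done <- FALSE
      for (try in seq_len(500L)) {
        cy <- runif(1, s$a + s$b + 2, nr - s$a - s$b - 2)
        cx <- runif(1, s$a + s$b + 2, nc - s$a - s$b - 2)
        em <- ellipse(cy, cx, s$a + 4, s$b + 4, s$ang)
        if (any(em & (patchLab > 0 | matrixLab > 0))) next
        matrixLab[ellipse(cy, cx, s$a, s$b, s$ang)] <- j
        done <- TRUE
        break
      }
      if (!done) stop("cannot place matrix ROI for patch ", j)
    }
  })
  img <- matrix(matrixIntensity, nr, nc)
  img[patchLab > 0] <- patchIntensity
  if (noiseSd > 0) {
    with_seed(derive_seed(seed, 17L), {
      img <- img + rnorm(length(img), sd = noiseSd)
    })
    img <- matrix(img, nr, nc)
  }
  list(image = PlanarImage(img), patchLabels = patchLab,
       matrixLabels = matrixLab,
       trueRatio = patchIntensity / matrixIntensity)
}
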