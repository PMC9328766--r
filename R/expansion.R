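## Expansion-factor estimation from a pre-/post-expansion image pair:
## keypoint descriptors are matched with a ratio test, a similarity
## transform x' = s R x + t is fit by random-sample consensus over
## match pairs, and the scale s is the linear expansion factor. In the
## complex-number parameterization z' = alpha z + beta used here,
## alpha = s exp(i theta), so s = |alpha|, which equals the square root
## of the determinant of the 2x2 linear block; reflections cannot arise
## in this parameterization.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = .GlobalEnv)
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = .GlobalEnv)),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

estimation_failure <- function(message, diagnostics = list()) {
  stop(errorCondition(message,
                      class = c("expansionEstimationError", "error",
                                "condition"),
                      diagnostics = diagnostics))
}

match_descriptors <- function(d1, d2, ratioThreshold) {
  if (nrow(d1) == 0 || nrow(d2) < 2)
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  # squared L2 distances via the Gram matrix
  n1 <- rowSums(d1^2)
  n2 <- rowSums(d2^2)
  D2 <- outer(n1, n2, "+") - 2 * tcrossprod(d1, d2)
  D2[D2 < 0] <- 0
  i <- integer(0); j <- integer(0); dd <- numeric(0)
  for (a in seq_len(nrow(d1))) {
    o <- order(D2[a, ])[1:2]
    best <- sqrt(D2[a, o[1]]); second <- sqrt(D2[a, o[2]])
    if (second <= 0 || best < ratioThreshold * second) {
      i <- c(i, a); j <- c(j, o[1]); dd <- c(dd, best)
    }
  }
  data.frame(i = i, j = j, dist = dd)
}

ls_similarity <- function(za, zb) {
  ma <- mean(za); mb <- mean(zb)
  alpha <- sum((zb - mb) * Conj(za - ma)) / sum(Mod(za - ma)^2)
  beta <- mb - alpha * ma
  list(alpha = alpha, beta = beta)
}

#' Estimate the linear expansion factor from an image pair
#'
#' Detects scale-invariant keypoints on the pre- and post-expansion
#' images, matches descriptors with a ratio test, and fits the
#' similarity transform `x' = s R x + t` by random-sample consensus
#' followed by least squares on the inliers. The recovered uniform
#' scale `s` is the linear expansion factor. Deterministic for a fixed
#' `seed`.
#'
#' Degenerate inputs (blank images, too few keypoints or matches) and
#' unsupported fits (fewer than `params$minInliers` consensus inliers)
#' raise a classed error of class `"expansionEstimationError"` carrying
#' the diagnostics, never a silent number.
#'
#' @param pre,post [PlanarImage-class] objects or numeric matrices.
#' @param params a [siftParams()] list.
#' @param seed integer seed for the consensus sampler (default 0).
#' @return An [ExpansionEstimate-class].
#' @examples
#' pair <- generateExpansionPair(textureSeed = 1, scale = 2)
#' est <- estimateExpansion(pair$pre, pair$post, seed = 0)
#' expansionScale(est)
#' @export
estimateExpansion <- function(pre, post, params = siftParams(), seed = 0) {
  kpre <- detectKeypoints(pre, params)
  kpost <- detectKeypoints(post, params)
  n1 <- nrow(kpre$keypoints); n2 <- nrow(kpost$keypoints)
  diag0 <- list(nKeypointsPre = n1, nKeypointsPost = n2)
  if (n1 < 4 || n2 < 4)
    estimation_failure("too few keypoints for estimation", diag0)
  m <- match_descriptors(kpre$descriptors, kpost$descriptors,
                         params$ratioThreshold)
  diag0$nMatches <- nrow(m)
  if (nrow(m) < max(2, params$minInliers))
    estimation_failure("too few descriptor matches for estimation", diag0)

  za <- complex(real = kpre$keypoints$col[m$i],
                imaginary = kpre$keypoints$row[m$i])
  zb <- complex(real = kpost$keypoints$col[m$j],
                imaginary = kpost$keypoints$row[m$j])
  nm <- length(za)
  thr <- params$ransacThreshold

  best <- NULL
  with_seed(seed, {
    bestCount <- 0
    bestRms <- Inf
    iter <- 0
    maxIter <- params$maxIterations
    while (iter < maxIter) {
      iter <- iter + 1
      s2 <- sample.int(nm, 2)
      if (za[s2[1]] == za[s2[2]]) next
      alpha <- (zb[s2[2]] - zb[s2[1]]) / (za[s2[2]] - za[s2[1]])
      if (!is.finite(Mod(alpha)) || Mod(alpha) <= 0) next
      beta <- zb[s2[1]] - alpha * za[s2[1]]
      resid <- Mod(alpha * za + beta - zb)
      inl <- resid < thr
      cnt <- sum(inl)
      if (cnt > bestCount ||
          (cnt == bestCount && cnt > 0 && mean(resid[inl]^2) < bestRms)) {
        bestCount <- cnt
        bestRms <- if (cnt > 0) mean(resid[inl]^2) else Inf
        best <- inl
        # adaptive stop: enough iterations for 99.9% confidence
        w <- cnt / nm
        if (w > 0.2) {
          need <- log(0.001) / log(1 - w^2)
          if (iter >= need) break
        }
      }
    }
  })
  if (is.null(best) || sum(best) < params$minInliers) {
    diag0$nInliers <- if (is.null(best)) 0L else sum(best)
    estimation_failure("too few consensus inliers for estimation", diag0)
  }

  # least-squares refinement with one inlier re-selection pass
  inl <- best
  for (pass in 1:2) {
    fit <- ls_similarity(za[inl], zb[inl])
    resid <- Mod(fit$alpha * za + fit$beta - zb)
    inl2 <- resid < thr
    if (sum(inl2) >= params$minInliers) inl <- inl2 else break
  }
  fit <- ls_similarity(za[inl], zb[inl])
  resid <- Mod(fit$alpha * za[inl] + fit$beta - zb[inl])
  new("ExpansionEstimate",
      scale = Mod(fit$alpha),
      rotation = Arg(fit$alpha) * 180 / pi,
      translation = c(Im(fit$beta), Re(fit$beta)),
      nKeypointsPre = as.integer(n1), nKeypointsPost = as.integer(n2),
      nMatches = as.integer(nm), nInliers = as.integer(sum(inl)),
      rmsInlierResidual = sqrt(mean(resid^2)))
}

#' Summarize expansion factors across estimates
#'
#' Arithmetic mean and standard error of the mean of the recovered
#' scales. With a single estimate the SEM is undefined; it is reported
#' as 0 with `semDefined = FALSE` so tabular outputs stay numeric.
#'
#' @param estimates a list of [ExpansionEstimate-class] objects, or a
#'   numeric vector of scales.
#' @return A one-row `data.frame`: `mean`, `sem`, `n`, `semDefined`.
#' @examples
#' summarizeFactors(c(3, 5))  # mean 4, sem 1
#' @export
summarizeFactors <- function(estimates) {
  scales <- if (is.numeric(estimates)) estimates
            else vapply(estimates, expansionScale, numeric(1))
  n <- length(scales)
  if (n == 0L) stop("at least one estimate is required")
  semDefined <- n > 1L
  data.frame(mean = mean(scales),
             sem = if (semDefined) sd(scales) / sqrt(n) else 0,
             n = n, semDefined = semDefined)
}
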