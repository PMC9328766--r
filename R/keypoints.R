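## Scale-invariant keypoint detection in the SIFT mould: a
## difference-of-Gaussian scale-space pyramid, 3D (x, y, scale) extrema
## with quadratic sub-pixel refinement and edge rejection, dominant
## gradient orientation assignment, and a 4 x 4 x 8 gradient-histogram
## descriptor sampled in the keypoint's scale- and rotation-normalized
## frame. Used by estimateExpansion() to recover the expansion factor.

#' Parameters for keypoint detection and matching
#'
#' @param nScalesPerOctave DoG intervals per octave (default 3).
#' @param sigma0 base blur of each octave in pixels (default 1.6).
#' @param contrastThreshold minimum refined |DoG| response, on images
#'   normalized to \[0, 1\] (default 0.02).
#' @param edgeThreshold principal-curvature ratio cutoff (default 10).
#' @param maxKeypoints cap on keypoints per image, strongest responses
#'   first (default 600).
#' @param ratioThreshold Lowe ratio-test cutoff for descriptor matches
#'   (default 0.75).
#' @param ransacThreshold inlier reprojection threshold in post-image
#'   pixels (default 3).
#' @param minInliers minimum consensus inliers for a valid fit
#'   (default 10).
#' @param maxIterations RANSAC iteration cap (default 2000).
#' @return A named list of parameters.
#' @export
siftParams <- function(nScalesPerOctave = 3, sigma0 = 1.6,
                       contrastThreshold = 0.02, edgeThreshold = 10,
                       maxKeypoints = 600, ratioThreshold = 0.75,
                       ransacThreshold = 3, minInliers = 10,
                       maxIterations = 2000) {
  list(nScalesPerOctave = nScalesPerOctave, sigma0 = sigma0,
       contrastThreshold = contrastThreshold, edgeThreshold = edgeThreshold,
       maxKeypoints = maxKeypoints, ratioThreshold = ratioThreshold,
       ransacThreshold = ransacThreshold, minInliers = minInliers,
       maxIterations = maxIterations)
}

grad_pair <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  gy <- matrix(0, nr, nc); gx <- matrix(0, nr, nc)
  if (nr > 2) gy[2:(nr - 1), ] <- (m[3:nr, ] - m[1:(nr - 2), ]) / 2
  if (nc > 2) gx[, 2:(nc - 1)] <- (m[, 3:nc] - m[, 1:(nc - 2)]) / 2
  list(gx = gx, gy = gy)
}

bilinear_sample <- function(m, r, c) {
  # r, c are 0-based fractional positions
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 0), nr - 1.0001)
  c <- pmin(pmax(c, 0), nc - 1.0001)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  m[cbind(r0 + 1, c0 + 1)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 2, c0 + 1)] * fr * (1 - fc) +
    m[cbind(r0 + 1, c0 + 2)] * (1 - fr) * fc +
    m[cbind(r0 + 2, c0 + 2)] * fr * fc
}

find_extrema <- function(D, thresh) {
  nr <- dim(D)[1]; nc <- dim(D)[2]; nl <- dim(D)[3]
  out <- NULL
  for (s in 2:(nl - 1)) {
    centre <- D[2:(nr - 1), 2:(nc - 1), s]
    mx <- matrix(-Inf, nr - 2, nc - 2)
    mn <- matrix(Inf, nr - 2, nc - 2)
    for (ds in -1:1) for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0 && ds == 0) next
      blk <- D[(2 + dr):(nr - 1 + dr), (2 + dc):(nc - 1 + dc), s + ds]
      mx <- pmax(mx, blk)
      mn <- pmin(mn, blk)
    }
    hit <- (centre > mx & centre > thresh) | (centre < mn & centre < -thresh)
    idx <- which(hit, arr.ind = TRUE)
    if (nrow(idx) > 0)
      out <- rbind(out, cbind(idx[, 1] + 1L, idx[, 2] + 1L,
                              rep(s, nrow(idx))))
  }
  if (is.null(out)) matrix(integer(0), 0, 3) else out
}

refine_candidate <- function(D, r, c, s, contrastThreshold, edgeThreshold) {
  g <- c((D[r + 1, c, s] - D[r - 1, c, s]) / 2,
         (D[r, c + 1, s] - D[r, c - 1, s]) / 2,
         (D[r, c, s + 1] - D[r, c, s - 1]) / 2)
  v0 <- D[r, c, s]
  Hrr <- D[r + 1, c, s] + D[r - 1, c, s] - 2 * v0
  Hcc <- D[r, c + 1, s] + D[r, c - 1, s] - 2 * v0
  Hss <- D[r, c, s + 1] + D[r, c, s - 1] - 2 * v0
  Hrc <- (D[r + 1, c + 1, s] - D[r + 1, c - 1, s] -
          D[r - 1, c + 1, s] + D[r - 1, c - 1, s]) / 4
  Hrs <- (D[r + 1, c, s + 1] - D[r + 1, c, s - 1] -
          D[r - 1, c, s + 1] + D[r - 1, c, s - 1]) / 4
  Hcs <- (D[r, c + 1, s + 1] - D[r, c + 1, s - 1] -
          D[r, c - 1, s + 1] + D[r, c - 1, s - 1]) / 4
  H <- matrix(c(Hrr, Hrc, Hrs, Hrc, Hcc, Hcs, Hrs, Hcs, Hss), 3, 3)
  off <- tryCatch(-solve(H, g), error = function(e) NULL)
  if (is.null(off) || any(!is.finite(off)) || any(abs(off) > 1.5)) return(NULL)
  val <- v0 + 0.5 * sum(g * off)
  if (abs(val) < contrastThreshold) return(NULL)
  tr <- Hrr + Hcc
  dt <- Hrr * Hcc - Hrc^2
  et <- edgeThreshold
  if (dt <= 0 || tr^2 / dt >= (et + 1)^2 / et) return(NULL)
  c(dr = off[1], dc = off[2], ds = off[3], val = val)
}

orientation_peaks <- function(gx, gy, r0, c0, sigma) {
  # r0, c0 are 0-based refined positions in level coordinates
  R <- max(4L, as.integer(round(4.5 * sigma)))
  nr <- nrow(gx); nc <- ncol(gx)
  rr <- max(1, round(r0) + 1 - R):min(nr, round(r0) + 1 + R)
  cc <- max(1, round(c0) + 1 - R):min(nc, round(c0) + 1 + R)
  sgx <- gx[rr, cc, drop = FALSE]; sgy <- gy[rr, cc, drop = FALSE]
  dr <- outer(rr - 1 - r0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - 1 - c0)
  w <- exp(-(dr^2 + dc^2) / (2 * (1.5 * sigma)^2))
  mag <- sqrt(sgx^2 + sgy^2)
  ang <- atan2(sgy, sgx) %% (2 * pi)
  bin <- (floor(ang / (2 * pi) * 36) %% 36) + 1
  h <- numeric(36)
  acc <- rowsum(as.numeric(w * mag), as.integer(bin))
  h[as.integer(rownames(acc))] <- acc
  for (it in 1:2)
    h <- (h + c(h[36], h[-36]) + c(h[-1], h[1])) / 3
  mx <- max(h)
  if (mx <= 0) return(numeric(0))
  left <- c(h[36], h[-36]); right <- c(h[-1], h[1])
  peaks <- which(h >= 0.8 * mx & h > left & h >= right)
  vapply(peaks, function(b) {
    l <- h[((b - 2) %% 36) + 1]; cb <- h[b]; rgt <- h[(b %% 36) + 1]
    den <- l - 2 * cb + rgt
    dbin <- if (abs(den) > 1e-12) 0.5 * (l - rgt) / den else 0
    ((b - 0.5 + dbin) / 36 * 2 * pi) %% (2 * pi)
  }, numeric(1))
}

descriptor_at <- function(gx, gy, r0, c0, sigma, theta) {
  h <- 0.8 * sigma
  t <- seq(-7.5, 7.5, by = 1)
  u <- rep(t, each = 16)   # rotated row axis
  v <- rep(t, times = 16)  # rotated column axis
  ct <- cos(theta); st <- sin(theta)
  drow <- h * (v * st + u * ct)
  dcol <- h * (v * ct - u * st)
  sgx <- bilinear_sample(gx, r0 + drow, c0 + dcol)
  sgy <- bilinear_sample(gy, r0 + drow, c0 + dcol)
  mag <- sqrt(sgx^2 + sgy^2)
  ang <- (atan2(sgy, sgx) - theta) %% (2 * pi)
  w <- exp(-(u^2 + v^2) / (2 * 8^2))
  iu <- pmin(pmax(floor((u + 8) / 4), 0), 3)
  iv <- pmin(pmax(floor((v + 8) / 4), 0), 3)
  ob <- (floor(ang / (2 * pi) * 8) %% 8)
  idx <- as.integer((iu * 4 + iv) * 8 + ob + 1)
  d <- numeric(128)
  acc <- rowsum(as.numeric(w * mag), idx)
  d[as.integer(rownames(acc))] <- acc
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d[d > 0.2] <- 0.2
  nrm <- sqrt(sum(d^2))
  if (nrm > 0) d <- d / nrm
  d
}

#' Detect scale-invariant keypoints and descriptors
#'
#' @param image a [PlanarImage-class] or numeric matrix; intensities are
#'   min-max normalized internally. A constant image yields zero
#'   keypoints.
#' @param params a [siftParams()] list.
#' @return A list with `keypoints` (data.frame: `row`, `col` 0-based
#'   pixel positions, `sigma`, `octave`, `angle` radians, `response`)
#'   and `descriptors` (matrix, one 128-vector per row).
#' @seealso [estimateExpansion()]
#' @export
detectKeypoints <- function(image, params = siftParams()) {
  img <- if (is(image, "PlanarImage")) volumeData(image) else as.matrix(image)
  emptyOut <- list(
    keypoints = data.frame(row = numeric(0), col = numeric(0),
                           sigma = numeric(0), octave = integer(0),
                           angle = numeric(0), response = numeric(0)),
    descriptors = matrix(0, 0, 128))
  rng <- range(img)
  if (!all(is.finite(rng)) || diff(rng) <= 0) return(emptyOut)
  img <- (img - rng[1]) / diff(rng)
  nS <- params$nScalesPerOctave
  k <- 2^(1 / nS)
  s0 <- params$sigma0
  nlev <- nS + 3
  sigs <- s0 * k^(0:(nlev - 1))

  # phase 1: Gaussian pyramid
  pyr <- list()
  base <- gauss_blur_cpp(img, sqrt(max(s0^2 - 0.25, 0.01)))
  repeat {
    G <- vector("list", nlev)
    G[[1]] <- base
    for (s in 2:nlev)
      G[[s]] <- gauss_blur_cpp(G[[s - 1]], sqrt(sigs[s]^2 - sigs[s - 1]^2))
    pyr[[length(pyr) + 1]] <- G
    nxt <- G[[nS + 1]]
    if (min(dim(nxt)) < 32 || length(pyr) >= 8) break
    base <- nxt[seq(1, nrow(nxt), 2), seq(1, ncol(nxt), 2)]
  }

  # phase 2: extrema + refinement
  cand <- NULL
  for (o in seq_along(pyr)) {
    G <- pyr[[o]]
    nr <- nrow(G[[1]]); nc <- ncol(G[[1]])
    if (nr < 10 || nc < 10) next
    D <- array(0, c(nr, nc, nlev - 1))
    for (s in 1:(nlev - 1)) D[, , s] <- G[[s + 1]] - G[[s]]
    ex <- find_extrema(D, 0.5 * params$contrastThreshold)
    for (i in seq_len(nrow(ex))) {
      r <- ex[i, 1]; c <- ex[i, 2]; s <- ex[i, 3]
      rf <- refine_candidate(D, r, c, s, params$contrastThreshold,
                             params$edgeThreshold)
      if (is.null(rf)) next
      cand <- rbind(cand, c(o, s, r - 1 + rf[1], c - 1 + rf[2],
                            s - 1 + rf[3], rf[4]))
    }
  }
  if (is.null(cand) || nrow(cand) == 0) return(emptyOut)
  colnames(cand) <- c("octave", "level", "r0", "c0", "sidx", "response")
  cand <- cand[order(-abs(cand[, "response"])), , drop = FALSE]
  if (nrow(cand) > params$maxKeypoints)
    cand <- cand[seq_len(params$maxKeypoints), , drop = FALSE]

  # phase 3: orientation + descriptors
  rows <- NULL
  descs <- NULL
  for (o in sort(unique(cand[, "octave"]))) {
    G <- pyr[[o]]
    sel <- which(cand[, "octave"] == o)
    gcache <- vector("list", nlev)
    for (i in sel) {
      lev <- as.integer(cand[i, "level"])
      if (is.null(gcache[[lev]])) gcache[[lev]] <- grad_pair(G[[lev]])
      gg <- gcache[[lev]]
      sigOct <- s0 * k^(cand[i, "sidx"])
      r0 <- cand[i, "r0"]; c0 <- cand[i, "c0"]
      angs <- orientation_peaks(gg$gx, gg$gy, r0, c0, sigOct)
      for (a in angs) {
        dvec <- descriptor_at(gg$gx, gg$gy, r0, c0, sigOct, a)
        rows <- rbind(rows, c(row = r0 * 2^(o - 1), col = c0 * 2^(o - 1),
                              sigma = sigOct * 2^(o - 1), octave = o - 1,
                              angle = a, response = cand[i, "response"]))
        descs <- rbind(descs, dvec)
      }
    }
  }
  if (is.null(rows)) return(emptyOut)
  kp <- as.data.frame(rows)
  kp$octave <- as.integer(kp$octave)
  rownames(descs) <- NULL
  list(keypoints = kp, descriptors = descs)
}
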