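# Shared fixtures and independent oracles, all built in code.

# brute-force flood-fill component labelling; the independent oracle
# for the scan-order BFS labelling used by the package
flood_fill_label <- function(arr, connectivity) {
  d <- dim(arr)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, d)
  nxt <- 0L
  for (i in which(arr)) {
    if (lab[i] != 0L) next
    nxt <- nxt + 1L
    queue <- i
    lab[i] <- nxt
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      pz <- (p - 1) %% d[1] + 1
      py <- ((p - 1) %/% d[1]) %% d[2] + 1
      px <- (p - 1) %/% (d[1] * d[2]) + 1
      for (k in seq_len(nrow(offs))) {
        q <- c(pz, py, px) + offs[k, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + d[1] * (q[2] - 1) + d[1] * d[2] * (q[3] - 1)
        if (arr[qi] && lab[qi] == 0L) {
          lab[qi] <- nxt
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# labels agree iff the partitions into components agree
same_partition <- function(lab1, lab2) {
  f1 <- as.integer(factor(lab1[lab1 > 0],
                          levels = unique(lab1[lab1 > 0])))
  f2 <- as.integer(factor(lab2[lab2 > 0],
                          levels = unique(lab2[lab2 > 0])))
  identical(which(lab1 > 0), which(lab2 > 0)) && identical(f1, f2)
}

# axis-aligned digital cylinder along z: voxel centres within r of the
# axis, flat ends, exact axial extent (len voxels)
make_digital_cylinder <- function(r, len, pad = 3) {
  ny <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  a <- array(FALSE, c(len, ny, ny))
  for (y in seq_len(ny)) for (x in seq_len(ny)) {
    if ((y - c0)^2 + (x - c0)^2 <= r^2) a[, y, x] <- TRUE
  }
  AxonMask(a)
}

# straight capsule tube of known centerline length via the generator
make_capsule_tube <- function(r, len, seed = 1) {
  generateAxonPhantom(phantomSpec(
    shape = c(len + 16, 2 * (r + 4) + 9, 2 * (r + 4) + 9),
    nAxons = 1, radius = r, tortuosity = 0, noiseSd = 0,
    start = c(8, r + 6, r + 6), direction = c(1, 0, 0),
    length = len, seed = seed))
}

random_prob_volume <- function(dims, seed) {
  set.seed(seed)
  ProbabilityVolume(array(runif(prod(dims)), dims))
}
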