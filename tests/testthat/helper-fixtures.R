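# Raster builders and independent brute-force oracles used across tests.
# Oracles are deliberately written as plain double loops, independent of the
# package's vectorized implementations.

make_region <- function(nr, nc, predicate) {
  m <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc))
    m[r, c] <- predicate(r, c)
  m
}

disk_region <- function(radius, pad = 4L) {
  n <- 2L * radius + 2L * pad + 1L
  ctr <- radius + pad + 1L
  make_region(n, n, function(r, c) (r - ctr)^2 + (c - ctr)^2 <= radius^2)
}

ellipse_region <- function(a, b, pad = 4L) {
  n <- 2L * max(a, b) + 2L * pad + 1L
  ctr <- max(a, b) + pad + 1L
  make_region(n, n, function(r, c)
    ((c - ctr) / a)^2 + ((r - ctr) / b)^2 <= 1)
}

# A simple disk-in-disk segmented cell with constant-ish intensities.
toy_cell <- function(r_nuc = 6L, r_cyto = 14L, size = 40L,
                     b_nuc = 100, b_cyto = 180, b_bg = 230, noise = 0) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  d <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  mask <- matrix(0L, size, size)
  mask[d <= r_cyto] <- 1L
  mask[d <= r_nuc] <- 2L
  img <- matrix(b_bg, size, size)
  img[mask == 1L] <- b_cyto
  img[mask == 2L] <- b_nuc
  if (noise > 0) img <- img + matrix(rnorm(size^2, sd = noise), size, size)
  img <- matrix(pmin(pmax(round(img), 0), 255), size, size)
  segmented_cell(img, mask)
}

# Oracle: ellipse axis lengths from second central moments, accumulated with
# an explicit loop over pixels.
oracle_axes <- function(region) {
  idx <- which(region, arr.ind = TRUE)
  n <- nrow(idx)
  mr <- mean(idx[, 1]); mc <- mean(idx[, 2])
  s20 <- 0; s02 <- 0; s11 <- 0
  for (i in seq_len(n)) {
    dr <- idx[i, 1] - mr; dc <- idx[i, 2] - mc
    s20 <- s20 + dr * dr; s02 <- s02 + dc * dc; s11 <- s11 + dr * dc
  }
  cov <- matrix(c(s20, s11, s11, s02) / n, 2, 2)
  ev <- sort(eigen(cov, symmetric = TRUE)$values, decreasing = TRUE)
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(max(ev[2], 0)))
}

# Oracle: strict local extrema by exhaustive 8-neighbour scan.
oracle_extrema <- function(intensity, region, mode) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  count <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!region[r, c]) next
    navail <- 0L; pass <- TRUE
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !region[rr, cc]) next
      navail <- navail + 1L
      ok <- if (mode == "max") intensity[r, c] > intensity[rr, cc]
            else intensity[r, c] < intensity[rr, cc]
      if (!ok) pass <- FALSE
    }
    if (navail > 0L && pass) count <- count + 1L
  }
  count
}

# Oracle: GLCM homogeneity by direct double loop over pixel pairs and levels.
oracle_glcm <- function(intensity, region, levels, offset) {
  q <- floor(intensity * levels / 256)
  q[q > levels - 1] <- levels - 1
  counts <- matrix(0, levels, levels)
  nr <- nrow(intensity); nc <- ncol(intensity)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    rr <- r + offset[1]; cc <- c + offset[2]
    if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
    if (!region[r, c] || !region[rr, cc]) next
    i <- q[r, c] + 1; j <- q[rr, cc] + 1
    counts[i, j] <- counts[i, j] + 1
    counts[j, i] <- counts[j, i] + 1
  }
  p <- counts / sum(counts)
  h <- 0
  for (i in seq_len(levels)) for (j in seq_len(levels))
    h <- h + p[i, j] / (1 + abs(i - j))
  h
}

# Oracle: direct evaluation of the fuzzy membership formula for one query.
oracle_membership <- function(u_rows, dists, m) {
  w <- dists^(-2 / (m - 1))
  colSums(u_rows * w) / sum(w)
}

# Embed a cell's frame into a larger constant frame at offset (dr, dc).
shift_cell <- function(cell, pad_to, dr, dc, bg = 230) {
  n <- nrow(cell$intensity); p <- ncol(cell$intensity)
  img <- matrix(bg, pad_to, pad_to)
  msk <- matrix(0L, pad_to, pad_to)
  img[dr + seq_len(n), dc + seq_len(p)] <- cell$intensity
  msk[dr + seq_len(n), dc + seq_len(p)] <- cell$mask
  segmented_cell(img, msk)
}
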