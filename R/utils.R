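# Internal numeric helpers shared across modules.

# Isotropic Gaussian kernel, truncated at 4 sigma, unit sum.
gaussianKernel <- function(sigmaPx) {
  r <- max(1L, ceiling(4 * sigmaPx))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigmaPx^2))
  k <- outer(g, g)
  k / sum(k)
}

# Laplacian-of-Gaussian kernel (negated so blobs give positive response),
# scale-normalized by sigma^2.
logKernel <- function(sigmaPx) {
  r <- max(2L, ceiling(4 * sigmaPx))
  x <- (-r):r
  xx <- outer(x^2, rep(1, length(x)))
  yy <- t(xx)
  s2 <- sigmaPx^2
  k <- -(1 / (pi * s2^2)) * (1 - (xx + yy) / (2 * s2)) *
    exp(-(xx + yy) / (2 * s2))
  k <- k - mean(k)          # zero DC response
  -k * s2                   # negate + scale-normalize
}

# 2-D convolution with replicated borders (EBImage FFT filter); images
# smaller than the kernel are replicate-padded first.
convolve2d <- function(mat, kernel) {
  padR <- max(0, nrow(kernel) - nrow(mat))
  padC <- max(0, ncol(kernel) - ncol(mat))
  if (padR == 0 && padC == 0)
    return(EBImage::filter2(mat, kernel, boundary = "replicate"))
  r0 <- ceiling(padR / 2); c0 <- ceiling(padC / 2)
  rows <- pmin(pmax(seq_len(nrow(mat) + padR) - r0, 1), nrow(mat))
  cols <- pmin(pmax(seq_len(ncol(mat) + padC) - c0, 1), ncol(mat))
  big <- mat[rows, cols, drop = FALSE]
  out <- EBImage::filter2(big, kernel, boundary = "replicate")
  out[r0 + seq_len(nrow(mat)), c0 + seq_len(ncol(mat)), drop = FALSE]
}

# Vectorized bilinear sampling of matrix `mat` at real-valued (row, col)
# coordinates (1-based). Out-of-range samples return NA.
bilinearSample <- function(mat, row, col) {
  nr <- nrow(mat); nc <- ncol(mat)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0;  fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & (r0 + (fr > 0)) <= nr & (c0 + (fc > 0)) <= nc
  out <- rep(NA_real_, length(row))
  if (!any(ok)) return(out)
  r0k <- r0[ok]; c0k <- c0[ok]; frk <- fr[ok]; fck <- fc[ok]
  r1k <- pmin(r0k + 1L, nr); c1k <- pmin(c0k + 1L, nc)
  v00 <- mat[cbind(r0k, c0k)]; v01 <- mat[cbind(r0k, c1k)]
  v10 <- mat[cbind(r1k, c0k)]; v11 <- mat[cbind(r1k, c1k)]
  out[ok] <- v00 * (1 - frk) * (1 - fck) + v01 * (1 - frk) * fck +
    v10 * frk * (1 - fck) + v11 * frk * fck
  out
}

# Deposit unit mass at real-valued (row, col) positions into a matrix by
# bilinear splatting; preserves the intensity centroid exactly.
splatPoints <- function(nr, nc, row, col, mass) {
  acc <- matrix(0, nr, nc)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0;  fc <- col - c0
  for (k in seq_along(row)) {
    for (dr in 0:1) for (dc in 0:1) {
      rr <- r0[k] + dr; cc <- c0[k] + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
        w <- (if (dr) fr[k] else 1 - fr[k]) * (if (dc) fc[k] else 1 - fc[k])
        acc[rr, cc] <- acc[rr, cc] + mass[k] * w
      }
    }
  }
  acc
}

# 8-connected labeling of a logical mask. EBImage::bwlabel is 4-connected,
# so diagonally adjacent labels are merged by union-find.
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n <= 1) return(lab)
  parent <- seq_len(n)
  findRoot <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- findRoot(i); rj <- findRoot(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs only (4-adjacency already merged by bwlabel)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]
  idx <- which(a > 0 & b > 0 & a != b)
  if (length(idx)) for (k in idx) unite(a[k], b[k])
  a <- lab[-nr, -1]; b <- lab[-1, -nc]
  idx <- which(a > 0 & b > 0 & a != b)
  if (length(idx)) for (k in idx) unite(a[k], b[k])
  roots <- vapply(seq_len(n), findRoot, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

# Local maxima of a 1-D signal with topographic prominence.
# Returns data.frame(pos, height, prominence); plateaus use their first index.
findPeaks1d <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(pos = integer(0), height = numeric(0),
                               prominence = numeric(0)))
  # rise then fall, flat tops reported at their first index
  pk <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) pk <- c(pk, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(pk)) return(data.frame(pos = integer(0), height = numeric(0),
                                     prominence = numeric(0)))
  prom <- vapply(pk, function(p) {
    h <- y[p]
    # walk left until a higher point or the border; track the minimum
    lmin <- h
    i <- p
    while (i > 1) { i <- i - 1; if (y[i] > h) break; lmin <- min(lmin, y[i]) }
    leftBase <- if (i >= 1 && y[i] > h) lmin else min(y[1:p])
    rmin <- h
    i <- p
    while (i < n) { i <- i + 1; if (y[i] > h) break; rmin <- min(rmin, y[i]) }
    rightBase <- if (i <= n && y[i] > h) rmin else min(y[p:n])
    h - max(leftBase, rightBase)
  }, numeric(1))
  data.frame(pos = pk, height = y[pk], prominence = prom)
}

# Parabolic sub-sample refinement of a discrete peak position.
refinePeak1d <- function(y, p) {
  n <- length(y)
  if (p <= 1 || p >= n) return(as.numeric(p))
  den <- y[p - 1] - 2 * y[p] + y[p + 1]
  if (abs(den) < 1e-12) return(as.numeric(p))
  off <- 0.5 * (y[p - 1] - y[p + 1]) / den
  as.numeric(p) + max(-0.5, min(0.5, off))
}

# Geodesic length of an ordered 8-connected pixel path: 1 per axial step,
# sqrt(2) per diagonal step.
pathStepLength <- function(path) {
  if (nrow(path) < 2) return(0)
  dr <- abs(diff(path[, 1])); dc <- abs(diff(path[, 2]))
  sum(ifelse(dr + dc == 2, sqrt(2), 1))
}

# Derive a stage seed from a master seed, kept well inside 32-bit range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 9973) %% 2147483629)
}
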