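#' ShiftParams: a translational chromatic-aberration correction
#'
#' The (dx, dy) pixel translation taking channel B onto channel A:
#' \code{mov = translate(ref, dx, dy)}. Estimated once from calibration images
#' and then applied (inverted) to every moving-channel frame.
#'
#' @slot dx,dy translation in pixels (columns, rows).
#' @export
setClass("ShiftParams", representation(dx = "numeric", dy = "numeric"))

setValidity("ShiftParams", function(object) {
  if (!is.finite(object@dx) || !is.finite(object@dy))
    return("shift components must be finite")
  TRUE
})

#' @rdname ShiftParams-class
#' @param dx,dy translation in pixels.
#' @export
shiftParams <- function(dx, dy) new("ShiftParams", dx = dx, dy = dy)

# Translate matrix content by (+dx columns, +dy rows) with bilinear
# resampling; out-of-range samples take `fill`. Integer shifts are exact.
translateImage <- function(mat, dx, dy, fill = 0) {
  nr <- nrow(mat); nc <- ncol(mat)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  v <- bilinearSample(mat, grid$row - dy, grid$col - dx)
  v[is.na(v)] <- fill
  matrix(v, nr, nc)
}

# FFT circular cross-correlation peak with parabolic sub-pixel refinement.
# Returns c(dx, dy) such that mov = translate(ref, dx, dy).
xcorrShift <- function(ref, mov) {
  ref <- ref - mean(ref); mov <- mov - mean(mov)
  if (sd(ref) == 0 || sd(mov) == 0)
    stop("registration window has zero variance; no structure to register")
  F1 <- stats::fft(ref); F2 <- stats::fft(mov)
  cc <- Re(stats::fft(Conj(F1) * F2, inverse = TRUE))
  nr <- nrow(cc); nc <- ncol(cc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  # parabolic refinement on circularly indexed neighbours
  at <- function(r, c) cc[(r - 1) %% nr + 1, (c - 1) %% nc + 1]
  refine <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (abs(den) < 1e-12) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
  }
  dr <- refine(at(pk[1] - 1, pk[2]), at(pk[1], pk[2]), at(pk[1] + 1, pk[2]))
  dc <- refine(at(pk[1], pk[2] - 1), at(pk[1], pk[2]), at(pk[1], pk[2] + 1))
  c(dx = unname(wrap(pk[2], nc)) + dc, dy = unname(wrap(pk[1], nr)) + dr)
}

#' Estimate the inter-channel translation from calibration stacks
#'
#' Both stacks are averaged over frames (calibration acquisitions typically
#' record ~10 frames of a stage micrometer per channel). For each of the four
#' regions of interest a window centered on the ROI is cross-correlated
#' between the averaged channels with sub-pixel (parabolic) peak
#' interpolation; the four estimates are combined component-wise by the
#' median, which tolerates one structureless or artifactual ROI.
#'
#' @param refStack,movStack list of \code{\link{MicroImage}} (or a single
#'   image) for the reference and moving channel.
#' @param rois data.frame with columns \code{row}, \code{col}: centers of the
#'   four 3x3-px regions of interest (any number >= 1 is accepted).
#' @param windowHalf half-size of the correlation window around each ROI, px.
#' @param maxShift maximum credible shift, px; larger estimates error.
#' @return a \code{\link{ShiftParams}}: \code{mov = translate(ref, dx, dy)}.
#' @seealso \code{\link{applyTranslation}}
#' @export
estimateTranslation <- function(refStack, movStack, rois, windowHalf = 16,
                                maxShift = 10) {
  asList <- function(x) if (is(x, "MicroImage")) list(x) else x
  refStack <- asList(refStack); movStack <- asList(movStack)
  if (!length(refStack) || !length(movStack)) stop("empty image stack")
  dims <- dim(pixels(refStack[[1]]))
  avg <- function(stack) {
    mats <- lapply(stack, function(im) {
      p <- pixels(im)
      if (!identical(dim(p), dims)) stop("stack frames differ in dimensions")
      p
    })
    Reduce(`+`, mats) / length(mats)
  }
  refM <- avg(refStack); movM <- avg(movStack)
  onePass <- function(mov) {
    ests <- apply(as.matrix(rois[, c("row", "col")]), 1, function(rc) {
      r0 <- round(rc[1]); c0 <- round(rc[2])
      if (r0 < 2 || c0 < 2 || r0 > dims[1] - 1 || c0 > dims[2] - 1)
        stop("ROI lies outside the frame")
      rr <- max(1, r0 - windowHalf):min(dims[1], r0 + windowHalf)
      cc <- max(1, c0 - windowHalf):min(dims[2], c0 + windowHalf)
      xcorrShift(refM[rr, cc], mov[rr, cc])
    })
    c(median(ests["dx", ]), median(ests["dy", ]))
  }
  # iterate: re-estimating after correcting removes the asymmetry bias of
  # the correlation-peak interpolation (integer shifts come out exact)
  s <- c(0, 0)
  for (it in 1:3) {
    delta <- onePass(if (all(s == 0)) movM
                     else translateImage(movM, -s[1], -s[2]))
    s <- s + delta
    if (max(abs(delta)) < 1e-4) break
  }
  # snap to an integer shift when the integer correction matches exactly
  sInt <- round(s)
  if (max(abs(s - sInt)) < 0.25) {
    movI <- translateImage(movM, -sInt[1], -sInt[2], fill = NA)
    diff <- abs(movI - refM)
    if (max(diff[!is.na(diff)]) <= 1e-8 * max(abs(refM))) s <- sInt
  }
  if (any(abs(s) > maxShift))
    stop(sprintf("estimated shift (%.2f, %.2f) exceeds the search radius %g",
                 s[1], s[2], maxShift))
  shiftParams(s[1], s[2])
}

#' Apply (invert) a chromatic-aberration translation to an image
#'
#' Resamples the image by the inverse of the estimated shift (bilinear), so
#' that a moving-channel image characterized by
#' \code{estimateTranslation(ref, mov)} is brought back onto the reference
#' channel. Border pixels without valid source samples are zeroed and marked
#' invalid in the \code{valid} mask; downstream statistics exclude them.
#'
#' @param img a \code{\link{MicroImage}}.
#' @param shift a \code{\link{ShiftParams}}.
#' @param maxShift guard radius, px.
#' @return the corrected \code{\link{MicroImage}}.
#' @export
applyTranslation <- function(img, shift, maxShift = 10) {
  stopifnot(is(img, "MicroImage"), is(shift, "ShiftParams"))
  if (abs(shift@dx) > maxShift || abs(shift@dy) > maxShift)
    stop("shift exceeds the configured search radius")
  mat <- pixels(img)
  nr <- nrow(mat); nc <- ncol(mat)
  grid <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  # inverse shift: content moves by (-dx, -dy)
  v <- bilinearSample(mat, grid$row + shift@dy, grid$col + shift@dx)
  valid <- matrix(!is.na(v), nr, nc) & validMask(img)
  v[is.na(v)] <- 0
  MicroImage(matrix(v, nr, nc), pixelSize = pixelSize(img),
             sizeUnit = img@sizeUnit, channel = channel(img), valid = valid)
}

# Grayscale erosion/dilation by a ball (spherical cap) structuring element.
ballMorph <- function(mat, radiusPx, op = c("erode", "dilate")) {
  op <- match.arg(op)
  r <- radiusPx
  off <- expand.grid(dr = -floor(r):floor(r), dc = -floor(r):floor(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, ]
  z <- sqrt(r^2 - off$dr^2 - off$dc^2) - r   # <= 0, cap height
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  rows <- seq_len(nr); cols <- seq_len(nc)
  for (k in seq_len(nrow(off))) {
    sr <- pmin(pmax(rows + off$dr[k], 1), nr)   # replicate border
    sc <- pmin(pmax(cols + off$dc[k], 1), nc)
    shifted <- mat[sr, sc, drop = FALSE]
    out <- if (op == "erode") pmin(out, shifted - z[k])
           else pmax(out, shifted + z[k])
  }
  out
}

# Classic rolling-ball background: grayscale opening with a ball element on a
# block-minimum downsampled grid, then bilinear upsampling.
rollingBallBackground <- function(mat, radius) {
  shrink <- if (radius <= 16) 1L else if (radius <= 32) 2L
            else if (radius <= 64) 4L else 8L
  nr <- nrow(mat); nc <- ncol(mat)
  # classic presmoothing: keeps the ball from riding into single-pixel noise
  if (shrink > 1) mat <- convolve2d(mat, matrix(1 / 9, 3, 3))
  if (shrink > 1) {
    # block-minimum downsampling, as in the classic algorithm: the background
    # must stay under the surface, and the presmoothing above keeps the
    # minimum from chasing single-pixel noise
    nrS <- ceiling(nr / shrink); ncS <- ceiling(nc / shrink)
    small <- matrix(Inf, nrS, ncS)
    for (dr in seq_len(shrink)) for (dc in seq_len(shrink)) {
      rows <- seq(dr, nr, by = shrink); cols <- seq(dc, nc, by = shrink)
      blk <- mat[rows, cols, drop = FALSE]
      small[seq_along(rows), seq_along(cols)] <-
        pmin(small[seq_along(rows), seq_along(cols)], blk)
    }
  } else small <- mat
  rS <- radius / shrink
  bg <- ballMorph(ballMorph(small, rS, "erode"), rS, "dilate")
  if (shrink > 1) {
    # bilinear upsample back to the full grid (block centers as knots)
    rowsUp <- (seq_len(nr) - 1) / shrink + 1 - (shrink - 1) / (2 * shrink)
    colsUp <- (seq_len(nc) - 1) / shrink + 1 - (shrink - 1) / (2 * shrink)
    rowsUp <- pmin(pmax(rowsUp, 1), nrow(bg))
    colsUp <- pmin(pmax(colsUp, 1), ncol(bg))
    grid <- expand.grid(row = rowsUp, col = colsUp)
    bg <- matrix(bilinearSample(bg, grid$row, grid$col), nr, nc)
  }
  bg
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale opening of the image by a
#' ball structuring element of the given radius (computed on a block-minimum
#' downsampled grid for large radii, as in the classic algorithm) and
#' subtracts it, clipping at zero. A constant image maps to zero everywhere;
#' features narrower than the ball are preserved.
#'
#' @param img a \code{\link{MicroImage}}.
#' @param radius ball radius in pixels (default 200).
#' @return the background-subtracted \code{\link{MicroImage}}.
#' @examples
#' im <- MicroImage(matrix(100, 64, 64))
#' max(pixels(subtractBackground(im, radius = 20)))
#' @export
subtractBackground <- function(img, radius = 200) {
  stopifnot(is(img, "MicroImage"))
  mat <- pixels(img)
  if (radius < 1 || radius >= min(dim(mat)))
    stop("radius must be >= 1 and smaller than the image dimensions")
  bg <- rollingBallBackground(mat, radius)
  out <- pmax(mat - bg, 0)
  MicroImage(out, pixelSize = pixelSize(img), sizeUnit = img@sizeUnit,
             channel = channel(img), valid = validMask(img))
}
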