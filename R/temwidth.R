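#' Straighten a fibril along a traced polyline
#'
#' Resamples the image along the arc-length-parameterized polyline at 1-px
#' steps, with perpendicular offsets in [-halfWindow, +halfWindow] (bilinear
#' interpolation). The result is a straightened band whose rows are the
#' perpendicular direction and whose columns follow the fibril axis, so each
#' column is a profile perpendicular to the local fibril direction.
#'
#' @param img a TEM \code{\link{MicroImage}} (nm calibration).
#' @param polyline matrix or data.frame with columns \code{x}, \code{y}
#'   (pixel coordinates of the traced fibril axis, >= 2 distinct points).
#' @param halfWindow half-width of the perpendicular band, px.
#' @return a \code{\link{FibrilTrace}}.
#' @export
straightenFibril <- function(img, polyline, halfWindow) {
  stopifnot(is(img, "MicroImage"))
  pl <- as.matrix(as.data.frame(polyline)[, c("x", "y")])
  if (nrow(pl) < 2) stop("polyline needs at least 2 points")
  seg <- sqrt(rowSums(diff(pl)^2))
  if (all(seg < 1e-9)) stop("polyline points coincide")
  pl <- pl[c(TRUE, seg > 1e-9), , drop = FALSE]
  seg <- sqrt(rowSums(diff(pl)^2))
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  sGrid <- seq(0, L, by = 1)
  i <- pmin(findInterval(sGrid, arc, rightmost.closed = TRUE), nrow(pl) - 1)
  f <- (sGrid - arc[i]) / seg[i]
  ctr <- pl[i, , drop = FALSE] + f * (pl[i + 1, , drop = FALSE] - pl[i, , drop = FALSE])
  tang <- (pl[i + 1, , drop = FALSE] - pl[i, , drop = FALSE]) / seg[i]
  normal <- cbind(-tang[, 2], tang[, 1])
  offs <- seq(-halfWindow, halfWindow, by = 1)
  mat <- pixels(img)
  band <- matrix(NA_real_, length(offs), length(sGrid))
  for (k in seq_along(offs)) {
    xs <- ctr[, 1] + offs[k] * normal[, 1]
    ys <- ctr[, 2] + offs[k] * normal[, 2]
    band[k, ] <- bilinearSample(mat, ys, xs)   # row = y, col = x
  }
  if (anyNA(band))
    stop("perpendicular band leaves the image frame; reduce halfWindow")
  new("FibrilTrace", polyline = pl, halfWindow = halfWindow,
      straightened = band, nmPerPx = pixelSize(img))
}

#' Fibril width from perpendicular edge-peak distances
#'
#' For each column of the straightened band, local intensity maxima with
#' topographic prominence above \code{promFraction} of the column's dynamic
#' range are detected; when at least two remain, the width is the distance
#' between the two most prominent peaks (sub-pixel parabolic refinement),
#' converted to nanometres. Columns with fewer than two peaks are excluded.
#' The negative-stain rim makes fibril edges bright; set \code{invert} for
#' dark-edge contrast.
#'
#' @param trace a \code{\link{FibrilTrace}}.
#' @param promFraction prominence threshold as a fraction of the column's
#'   dynamic range (default 0.1).
#' @param invert invert contrast before peak finding.
#' @return a \code{\link{WidthProfile}} (median and quartiles in nm).
#' @examples
#' img <- renderTemFibril(150, 600, nmPerPx = 1)
#' tr <- straightenFibril(img, data.frame(x = c(25, 595), y = c(90, 90)), 85)
#' profileWidth(tr)
#' @export
profileWidth <- function(trace, promFraction = 0.1, invert = FALSE) {
  stopifnot(is(trace, "FibrilTrace"))
  band <- trace@straightened
  if (invert) band <- max(band) - band
  widths <- apply(band, 2, function(col) {
    rngC <- diff(range(col))
    if (rngC == 0) return(NA_real_)
    pk <- findPeaks1d(col)
    pk <- pk[pk$prominence >= promFraction * rngC, , drop = FALSE]
    if (nrow(pk) < 2) return(NA_real_)
    pk <- pk[order(pk$prominence, decreasing = TRUE)[1:2], ]
    p <- vapply(pk$pos, function(i) refinePeak1d(col, i), numeric(1))
    abs(diff(p)) * trace@nmPerPx
  })
  ok <- widths[is.finite(widths)]
  if (!length(ok)) stop("no column yielded a two-peak width")
  qs <- unname(quantile(ok, c(0.25, 0.5, 0.75), type = 6))
  new("WidthProfile", widths = widths, median = qs[2], q1 = qs[1], q3 = qs[3],
      nColumns = length(ok))
}

#' Read a fibril polyline CSV (ordered x,y in px)
#'
#' @param path CSV with columns \code{x}, \code{y}.
#' @return data.frame with columns x, y.
#' @export
readPolylineCsv <- function(path) {
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df))) stop("polyline CSV needs x,y columns")
  df[, c("x", "y")]
}
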