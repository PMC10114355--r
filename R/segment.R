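#' AggregateRegion: one detected aggregate
#'
#' A connected component of above-threshold pixels, with its pixel
#' coordinates, area, integrated intensity, bounding box and centroid.
#'
#' @slot id integer; ids are assigned in order of descending area.
#' @slot pixelCoords n x 2 integer matrix of (row, col) pixels.
#' @slot area pixel count.
#' @slot totalIntensity summed intensity over the region, a.u.
#' @slot bbox (row0, col0, row1, col1), half-open.
#' @slot centroid intensity-weighted (row, col) center.
#' @slot edgeFlag TRUE when the region touches the frame border; length and
#'   width statistics exclude such regions by default.
#' @slot pixelSize physical pixel size inherited from the image.
#' @export
setClass("AggregateRegion",
  representation(id = "integer", pixelCoords = "matrix", area = "integer",
    totalIntensity = "numeric", bbox = "numeric", centroid = "numeric",
    edgeFlag = "logical", pixelSize = "numeric"))

setValidity("AggregateRegion", function(object) {
  if (object@area != nrow(object@pixelCoords))
    return("area must equal the number of pixels")
  if (anyDuplicated(paste(object@pixelCoords[, 1], object@pixelCoords[, 2])))
    return("pixels must be unique")
  TRUE
})

setMethod("show", "AggregateRegion", function(object) {
  cat(sprintf("AggregateRegion %d: %d px, total %.4g a.u., centroid (%.1f, %.1f)%s\n",
              object@id, object@area, object@totalIntensity,
              object@centroid[1], object@centroid[2],
              if (object@edgeFlag) " [edge]" else ""))
})

#' Detect aggregates as thresholded connected components
#'
#' Pixels strictly above the intensity threshold are grouped into connected
#' components (8-connectivity by default); components whose area is strictly
#' greater than \code{minAreaExclusive} are kept ("more than 9 pixels" is read
#' strictly: at least 10). The input is expected to be background-subtracted.
#' Regions are returned sorted by descending area with stable ids; pixels
#' marked invalid by registration are ignored.
#'
#' @param img a background-subtracted \code{\link{MicroImage}}.
#' @param intensityThreshold detection threshold, a.u. out of 65535
#'   (default 60; use 250 for kinetics imaging).
#' @param minAreaExclusive exclusive minimum area, px (default 9).
#' @param connectivity 8 (default) or 4.
#' @return list of \code{\link{AggregateRegion}}.
#' @examples
#' m <- matrix(0, 16, 16); m[4:5, 3:7] <- 100
#' regs <- segmentAggregates(MicroImage(m))
#' regs[[1]]@area
#' @export
segmentAggregates <- function(img, intensityThreshold = 60,
                              minAreaExclusive = 9, connectivity = 8) {
  stopifnot(is(img, "MicroImage"))
  if (intensityThreshold < 0 || intensityThreshold > 65535)
    stop("intensityThreshold must lie in [0, 65535]")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  mat <- pixels(img)
  mask <- mat > intensityThreshold & validMask(img)
  lab <- if (connectivity == 8) label8(mask) else EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  nr <- nrow(mat); nc <- ncol(mat)
  regions <- list()
  areas <- tabulate(labs, n)
  keep <- which(areas > minAreaExclusive)
  if (!length(keep)) return(list())
  ord <- keep[order(areas[keep], decreasing = TRUE)]
  out <- vector("list", length(ord))
  for (k in seq_along(ord)) {
    l <- ord[k]
    px <- idx[labs == l, , drop = FALSE]
    ints <- mat[px]
    w <- ints / sum(ints)
    out[[k]] <- new("AggregateRegion", id = k,
      pixelCoords = px, area = as.integer(nrow(px)),
      totalIntensity = sum(ints),
      bbox = c(min(px[, 1]), min(px[, 2]), max(px[, 1]) + 1, max(px[, 2]) + 1),
      centroid = c(sum(px[, 1] * w), sum(px[, 2] * w)),
      edgeFlag = any(px[, 1] %in% c(1L, nr) | px[, 2] %in% c(1L, nc)),
      pixelSize = pixelSize(img))
  }
  out
}

# binary mask of a region on the full image grid
regionMask <- function(region, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  m[region@pixelCoords] <- TRUE
  m
}

#' Paired intensity line profiles across two channels
#'
#' Samples both (registered) channels along a line with bilinear interpolation
#' at 1-px steps, min-max normalizes each profile to [0, 1], and reports the
#' Pearson correlation of the raw samples -- the colocalization readout for a
#' two-channel aggregate image.
#'
#' @param imgA,imgB two \code{\link{MicroImage}}s of equal size.
#' @param line numeric (r0, c0, r1, c1): line endpoints in pixels.
#' @param step sampling step, px.
#' @return list with \code{distance} (px), \code{profileA}, \code{profileB}
#'   (normalized), and \code{correlation}.
#' @export
lineProfile <- function(imgA, imgB, line, step = 1) {
  stopifnot(is(imgA, "MicroImage"), is(imgB, "MicroImage"))
  if (!identical(dim(pixels(imgA)), dim(pixels(imgB))))
    stop("channel images must have equal dimensions")
  p0 <- line[1:2]; p1 <- line[3:4]
  len <- sqrt(sum((p1 - p0)^2))
  if (len < step) stop("line endpoints coincide (or are closer than one step)")
  dims <- dim(pixels(imgA))
  if (any(c(p0, p1) < 1) || p0[1] > dims[1] || p1[1] > dims[1] ||
      p0[2] > dims[2] || p1[2] > dims[2])
    stop("line endpoints must lie inside the frame")
  t <- seq(0, 1, by = step / len)
  rr <- p0[1] + t * (p1[1] - p0[1])
  cc <- p0[2] + t * (p1[2] - p0[2])
  a <- bilinearSample(pixels(imgA), rr, cc)
  b <- bilinearSample(pixels(imgB), rr, cc)
  norm01 <- function(x) if (diff(range(x)) == 0) rep(0, length(x))
                        else (x - min(x)) / diff(range(x))
  list(distance = t * len, profileA = norm01(a), profileB = norm01(b),
       correlation = stats::cor(a, b))
}
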