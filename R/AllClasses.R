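#' @import methods
#' @importFrom stats median quantile sd fft rnorm rpois runif coef predict
#'   prcomp kmeans cor setNames dist residuals
#' @importFrom utils head tail read.csv write.csv
#' @importFrom tools md5sum
NULL

#' MicroImage: a calibrated 2-D intensity raster
#'
#' The central image container: a numeric pixel matrix (rows = y, columns = x)
#' on the 16-bit camera scale (0--65535 a.u.), with a physical pixel size and a
#' channel tag. TEM images use nanometre calibration; fluorescence images use
#' micrometres per pixel.
#'
#' @slot pixels numeric matrix of intensities (a.u.), all finite and >= 0.
#' @slot pixelSize physical size of one pixel, in the unit given by
#'   \code{sizeUnit} (default micrometres).
#' @slot sizeUnit \code{"um"} or \code{"nm"} per pixel.
#' @slot channel one of \code{"mCherry"}, \code{"ThT"}, \code{"TEM"}.
#' @slot valid logical matrix marking pixels invalidated by resampling
#'   (registration borders); same dimensions as \code{pixels}.
#'
#' @examples
#' img <- MicroImage(matrix(0, 32, 32), pixelSize = 0.1625, channel = "mCherry")
#' pixelSize(img)
#' @export
setClass("MicroImage",
  representation(pixels = "matrix", pixelSize = "numeric",
                 sizeUnit = "character", channel = "character",
                 valid = "matrix"),
  prototype(pixelSize = 0.1625, sizeUnit = "um", channel = "mCherry"))

setValidity("MicroImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be numeric")
  if (any(!is.finite(p))) return("pixel intensities must all be finite")
  if (any(p < 0)) return("pixel intensities must be >= 0")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0) return("pixelSize must be a single positive number")
  if (!object@sizeUnit %in% c("um", "nm")) return("sizeUnit must be 'um' or 'nm'")
  if (!object@channel %in% c("mCherry", "ThT", "TEM"))
    return("channel must be one of mCherry, ThT, TEM")
  if (length(object@valid) && !identical(dim(object@valid), dim(p)))
    return("valid mask dimensions must match pixels")
  TRUE
})

#' @rdname MicroImage-class
#' @param pixels numeric matrix of intensities.
#' @param pixelSize physical pixel size.
#' @param sizeUnit "um" or "nm".
#' @param channel channel tag.
#' @param valid optional logical validity mask.
#' @return a \code{MicroImage} object.
#' @export
MicroImage <- function(pixels, pixelSize = 0.1625, sizeUnit = "um",
                       channel = "mCherry", valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nrow(pixels), ncol(pixels))
  new("MicroImage", pixels = pixels, pixelSize = pixelSize,
      sizeUnit = sizeUnit, channel = channel, valid = valid)
}

#' SkeletonGraph: the topological skeleton of an aggregate as a graph
#'
#' Nodes sit at skeleton endpoints (degree 1) and junctions (degree >= 3);
#' edges are junction-free pixel paths with geodesic lengths (axial steps count
#' 1 px, diagonal steps sqrt(2) px, times the pixel size). Branch points are
#' nodes of degree >= 3. A closed skeleton with no endpoints is flagged as a
#' ring and its longest chain is the cycle circumference.
#'
#' @slot nodes data.frame with columns \code{row}, \code{col}, \code{degree}.
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{length} (physical units); \code{paths} holds the pixel coordinates.
#' @slot paths list of 2-column matrices (row, col) of the edge pixel paths.
#' @slot totalLength numeric, sum of edge lengths.
#' @slot longestChainLength numeric.
#' @slot longestChainPath matrix of (row, col) pixels along the longest chain.
#' @slot nBranchPoints integer.
#' @slot ringFlag logical.
#' @slot pixelSize numeric.
#' @export
setClass("SkeletonGraph",
  representation(nodes = "data.frame", edges = "data.frame", paths = "list",
                 totalLength = "numeric", longestChainLength = "numeric",
                 longestChainPath = "matrix", nBranchPoints = "integer",
                 ringFlag = "logical", pixelSize = "numeric"))

setValidity("SkeletonGraph", function(object) {
  if (object@longestChainLength > object@totalLength + 1e-9)
    return("longest chain cannot exceed total length")
  if (nrow(object@nodes) &&
      object@nBranchPoints != sum(object@nodes$degree >= 3))
    return("branch point count must equal number of degree>=3 nodes")
  if (nrow(object@edges) &&
      abs(object@totalLength - sum(object@edges$length)) >
        1e-6 * max(1, object@totalLength))
    return("total length must equal the sum of edge lengths")
  TRUE
})

#' KineticsTrace: a ThT intensity time course
#'
#' @slot times minutes, strictly increasing uniform grid.
#' @slot intensity a.u., one value per time point.
#' @slot condition one of "unseeded", "seeded", "blank", "monomer-free".
#' @slot replicateId integer replicate label.
#' @export
setClass("KineticsTrace",
  representation(times = "numeric", intensity = "numeric",
                 condition = "character", replicateId = "integer"),
  prototype(condition = "unseeded", replicateId = 1L))

setValidity("KineticsTrace", function(object) {
  if (length(object@times) != length(object@intensity))
    return("times and intensity must have equal length")
  if (length(object@times) > 1) {
    dt <- diff(object@times)
    if (any(dt <= 0)) return("times must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * mean(dt))
      return("times must be uniformly spaced")
  }
  if (any(!is.finite(object@intensity))) return("intensities must be finite")
  if (!object@condition %in% c("unseeded", "seeded", "blank", "monomer-free"))
    return("unknown condition tag")
  TRUE
})

#' @rdname KineticsTrace-class
#' @param times,intensity numeric vectors (minutes, a.u.).
#' @param condition condition tag.
#' @param replicateId integer replicate label.
#' @return a \code{KineticsTrace}.
#' @export
KineticsTrace <- function(times, intensity, condition = "unseeded",
                          replicateId = 1L) {
  new("KineticsTrace", times = as.numeric(times),
      intensity = as.numeric(intensity), condition = condition,
      replicateId = as.integer(replicateId))
}

#' KineticsFit: logistic parameterization of an aggregation time course
#'
#' The model is \code{baseline + amplitude / (1 + exp(-rate (t - tMid)))}.
#' The lag time is the intercept of the maximum-slope tangent with the
#' baseline, \code{tMid - 2/rate} for the logistic; the plateau time is the
#' first time the fitted curve reaches baseline + 0.95 amplitude,
#' \code{tMid + log(19)/rate}.
#'
#' @slot baseline,amplitude,tMid,growthRate,lagTime,plateauTime,rmse numerics.
#' @slot lagDefined logical; FALSE for flat traces (amplitude ~ 0).
#' @slot condition,replicateId provenance tags copied from the trace.
#' @export
setClass("KineticsFit",
  representation(baseline = "numeric", amplitude = "numeric", tMid = "numeric",
                 growthRate = "numeric", lagTime = "numeric",
                 plateauTime = "numeric", rmse = "numeric",
                 lagDefined = "logical", condition = "character",
                 replicateId = "integer"))

setValidity("KineticsFit", function(object) {
  if (object@amplitude < 0) return("amplitude must be >= 0")
  if (object@lagDefined) {
    if (!(object@lagTime < object@tMid && object@tMid < object@plateauTime))
      return("lag < tMid < plateau must hold for a defined fit")
  }
  TRUE
})

#' FibrilTrace: a straightened fibril band from a TEM image
#'
#' @slot polyline matrix of (x, y) pixel coordinates along the fibril axis.
#' @slot halfWindow half-width of the perpendicular band in pixels.
#' @slot straightened matrix; rows are perpendicular offsets
#'   (-halfWindow..halfWindow), columns arc-length positions.
#' @slot nmPerPx calibration (nm / pixel).
#' @export
setClass("FibrilTrace",
  representation(polyline = "matrix", halfWindow = "numeric",
                 straightened = "matrix", nmPerPx = "numeric"))

#' WidthProfile: per-column fibril widths from a straightened TEM band
#'
#' @slot widths nm per straightened column; NA where fewer than 2 peaks.
#' @slot median,q1,q3 summary statistics over defined columns (nm).
#' @slot nColumns number of columns with a defined width.
#' @export
setClass("WidthProfile",
  representation(widths = "numeric", median = "numeric", q1 = "numeric",
                 q3 = "numeric", nColumns = "integer"))

setValidity("WidthProfile", function(object) {
  w <- object@widths[is.finite(object@widths)]
  if (length(w)) {
    if (any(w <= 0)) return("defined widths must be > 0")
    if (object@median < min(w) - 1e-9 || object@median > max(w) + 1e-9)
      return("median must lie within the range of defined widths")
  }
  TRUE
})
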