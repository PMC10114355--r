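#' @name accessors
#' @title Accessors for aggremorph classes
#' @param object an aggremorph S4 object.
#' @return the slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "MicroImage", function(object) object@pixels)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "MicroImage", function(object) object@pixelSize)
#' @rdname accessors
#' @export
setMethod("pixelSize", "SkeletonGraph", function(object) object@pixelSize)

#' @rdname accessors
#' @export
setGeneric("channel", function(object) standardGeneric("channel"))
#' @rdname accessors
#' @export
setMethod("channel", "MicroImage", function(object) object@channel)

#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setMethod("validMask", "MicroImage", function(object) object@valid)

#' @rdname accessors
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))
#' @rdname accessors
#' @export
setMethod("totalLength", "SkeletonGraph", function(object) object@totalLength)

#' @rdname accessors
#' @export
setGeneric("longestChainLength",
           function(object) standardGeneric("longestChainLength"))
#' @rdname accessors
#' @export
setMethod("longestChainLength", "SkeletonGraph",
          function(object) object@longestChainLength)

#' @rdname accessors
#' @export
setGeneric("nBranchPoints", function(object) standardGeneric("nBranchPoints"))
#' @rdname accessors
#' @export
setMethod("nBranchPoints", "SkeletonGraph",
          function(object) object@nBranchPoints)

#' @rdname accessors
#' @export
setGeneric("ringFlag", function(object) standardGeneric("ringFlag"))
#' @rdname accessors
#' @export
setMethod("ringFlag", "SkeletonGraph", function(object) object@ringFlag)

#' @rdname accessors
#' @export
setGeneric("traceTimes", function(object) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setMethod("traceTimes", "KineticsTrace", function(object) object@times)

#' @rdname accessors
#' @export
setGeneric("traceIntensity", function(object) standardGeneric("traceIntensity"))
#' @rdname accessors
#' @export
setMethod("traceIntensity", "KineticsTrace", function(object) object@intensity)

#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname accessors
#' @export
setMethod("condition", "KineticsTrace", function(object) object@condition)
#' @rdname accessors
#' @export
setMethod("condition", "KineticsFit", function(object) object@condition)

#' @rdname accessors
#' @export
setGeneric("lagTime", function(object) standardGeneric("lagTime"))
#' @rdname accessors
#' @export
setMethod("lagTime", "KineticsFit",
          function(object) if (object@lagDefined) object@lagTime else NA_real_)

#' @rdname accessors
#' @export
setGeneric("plateauTime", function(object) standardGeneric("plateauTime"))
#' @rdname accessors
#' @export
setMethod("plateauTime", "KineticsFit",
          function(object) if (object@lagDefined) object@plateauTime else NA_real_)

#' @rdname accessors
#' @export
setGeneric("fibrilWidths", function(object) standardGeneric("fibrilWidths"))
#' @rdname accessors
#' @export
setMethod("fibrilWidths", "WidthProfile", function(object) object@widths)

setMethod("show", "MicroImage", function(object) {
  cat(sprintf("MicroImage: %d x %d px, %s channel, %.4g %s/px, range [%.4g, %.4g] a.u.\n",
              nrow(object@pixels), ncol(object@pixels), object@channel,
              object@pixelSize, object@sizeUnit,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf(paste0("SkeletonGraph: %d nodes, %d edges | total %.3g, ",
                     "longest chain %.3g | %d branch point(s)%s\n"),
              nrow(object@nodes), nrow(object@edges), object@totalLength,
              object@longestChainLength, object@nBranchPoints,
              if (object@ringFlag) " [ring]" else ""))
})

setMethod("show", "KineticsTrace", function(object) {
  cat(sprintf("KineticsTrace: %s replicate %d, %d points, t = %.0f..%.0f min\n",
              object@condition, object@replicateId, length(object@times),
              min(object@times), max(object@times)))
})

setMethod("show", "KineticsFit", function(object) {
  if (object@lagDefined)
    cat(sprintf(paste0("KineticsFit (%s): lag %.1f min, plateau %.1f min, ",
                       "amplitude %.3g a.u., rate %.3g /min, rmse %.3g\n"),
                object@condition, object@lagTime, object@plateauTime,
                object@amplitude, object@growthRate, object@rmse))
  else
    cat(sprintf("KineticsFit (%s): flat trace, amplitude ~ 0, lag undefined\n",
                object@condition))
})

setMethod("show", "WidthProfile", function(object) {
  cat(sprintf("WidthProfile: median %.3g nm [%.3g-%.3g], n = %d columns\n",
              object@median, object@q1, object@q3, object@nColumns))
})

setMethod("show", "FibrilTrace", function(object) {
  cat(sprintf("FibrilTrace: %d polyline points, band %d x %d px, %.3g nm/px\n",
              nrow(object@polyline), nrow(object@straightened),
              ncol(object@straightened), object@nmPerPx))
})
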