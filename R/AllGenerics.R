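#' @rdname Chromatogram-class
#' @param object,x a \code{Chromatogram}.
#' @export
setGeneric("baseCalls", function(x) standardGeneric("baseCalls"))
#' @rdname Chromatogram-class
#' @export
setGeneric("phredQualities", function(x) standardGeneric("phredQualities"))
#' @rdname Chromatogram-class
#' @export
setGeneric("peakLocations", function(x) standardGeneric("peakLocations"))
#' @rdname Chromatogram-class
#' @export
setGeneric("traceMatrix", function(x) standardGeneric("traceMatrix"))
#' @rdname Chromatogram-class
#' @export
setGeneric("channelOrder", function(x) standardGeneric("channelOrder"))
#' @rdname Chromatogram-class
#' @export
setGeneric("plateId", function(x) standardGeneric("plateId"))
#' @rdname Chromatogram-class
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname Chromatogram-class
#' @export
setMethod("baseCalls", "Chromatogram", function(x) x@baseCalls)
#' @rdname Chromatogram-class
#' @export
setMethod("phredQualities", "Chromatogram", function(x) x@qualities)
#' @rdname Chromatogram-class
#' @export
setMethod("peakLocations", "Chromatogram", function(x) x@peakLocations)
#' @rdname Chromatogram-class
#' @export
setMethod("traceMatrix", "Chromatogram", function(x) x@traces)
#' @rdname Chromatogram-class
#' @export
setMethod("channelOrder", "Chromatogram", function(x) x@channelOrder)
#' @rdname Chromatogram-class
#' @export
setMethod("plateId", "Chromatogram", function(x) x@plateId)
#' @rdname Chromatogram-class
#' @export
setMethod("wellId", "Chromatogram", function(x) x@wellId)

#' @rdname Chromatogram-class
#' @export
setMethod("length", "Chromatogram", function(x) nchar(x@baseCalls))

setMethod("show", "Chromatogram", function(object) {
  n <- nchar(object@baseCalls)
  cat("Chromatogram of", n, "called bases\n")
  if (nzchar(object@plateId) || nzchar(object@wellId)) {
    cat("  plate:", object@plateId, " well:", object@wellId, "\n")
  }
  cat("  channel order:", object@channelOrder,
      " trace samples:", nrow(object@traces), "\n")
  if (n) {
    cat("  mean Phred quality:",
        round(mean(object@qualities), 2), "\n")
  }
  invisible(NULL)
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  for (s in slotNames(object)) {
    cat(sprintf("  %-24s %g\n", s, slot(object, s)))
  }
  invisible(NULL)
})

setMethod("show", "GateConfig", function(object) {
  cat("GateConfig with", length(object@probes), "probe gate(s)\n")
  if (length(object@probes)) {
    for (i in seq_along(object@probes)) {
      cat(sprintf("  %s: %s >= %g\n", object@probes[i],
                  object@channels[i], object@thresholds[i]))
    }
  }
  invisible(NULL)
})
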