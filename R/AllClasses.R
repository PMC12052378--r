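#' @import methods
NULL

#' Chromatogram: one parsed Sanger trace
#'
#' Container for the analysed content of one ABIF (".ab1") trace file:
#' the four dye-channel signals, the called bases with their Phred
#' qualities, and the trace-sample index of each call's peak.
#'
#' @slot sourcePath path the trace was read from ("" for in-memory objects).
#' @slot plateId name of the containing plate folder.
#' @slot wellId canonical well label (row letter + two-digit column, "A01").
#' @slot channelOrder four-letter string over G/A/T/C giving the dye order
#'   of the trace columns (ABIF tag \code{FWO_}).
#' @slot traces integer matrix, one column per channel in
#'   \code{channelOrder} order, of non-negative analysed intensities
#'   (ABIF tags \code{DATA} 9--12).
#' @slot peakLocations integer vector of 0-based trace-sample indices, one
#'   per called base (ABIF tag \code{PLOC}); strictly increasing and always
#'   less than the number of trace rows.
#' @slot baseCalls called bases as a single string over A/C/G/T/N
#'   (ABIF tag \code{PBAS}).
#' @slot qualities integer vector of per-base Phred scores in 0--62
#'   (ABIF tag \code{PCON}).
#'
#' @examples
#' cg <- makeChromatogram(length = 20, quality = "good", seed = 1)
#' cg
#' nchar(baseCalls(cg))
#' @export
setClass("Chromatogram",
  representation(
    sourcePath = "character",
    plateId = "character",
    wellId = "character",
    channelOrder = "character",
    traces = "matrix",
    peakLocations = "integer",
    baseCalls = "character",
    qualities = "integer"
  ),
  prototype(
    sourcePath = "", plateId = "", wellId = "",
    channelOrder = "GATC",
    traces = matrix(integer(0), ncol = 4,
      dimnames = list(NULL, c("G", "A", "T", "C"))),
    peakLocations = integer(0),
    baseCalls = "",
    qualities = integer(0)
  )
)

setValidity("Chromatogram", function(object) {
  msg <- character(0)
  n <- nchar(object@baseCalls)
  if (length(object@baseCalls) != 1L) {
    msg <- c(msg, "baseCalls must be a single string")
  }
  if (!grepl("^[ACGTN]*$", object@baseCalls)) {
    msg <- c(msg, "baseCalls may contain only A, C, G, T, N")
  }
  if (length(object@qualities) != n || length(object@peakLocations) != n) {
    msg <- c(msg,
      "baseCalls, qualities and peakLocations must have equal length")
  }
  if (ncol(object@traces) != 4L) {
    msg <- c(msg, "traces must have four channels")
  }
  if (!identical(sort(strsplit(object@channelOrder, "")[[1]]),
                 c("A", "C", "G", "T"))) {
    msg <- c(msg, "channelOrder must be a permutation of G, A, T, C")
  }
  if (length(object@traces) && any(object@traces < 0)) {
    msg <- c(msg, "trace intensities must be non-negative")
  }
  if (any(object@qualities < 0L | object@qualities > 62L)) {
    msg <- c(msg, "qualities must be Phred scores in [0, 62]")
  }
  if (n > 0L) {
    if (any(diff(object@peakLocations) <= 0L)) {
      msg <- c(msg, "peakLocations must be strictly increasing")
    }
    if (any(object@peakLocations < 0L) ||
        any(object@peakLocations >= nrow(object@traces))) {
      msg <- c(msg, "peakLocations must index into the trace arrays")
    }
  }
  if (length(msg)) msg else TRUE
})

#' FilterConfig: thresholds for sequence quality filtering
#'
#' All pass/fail thresholds applied to per-sequence quality metrics, the
#' user-set approximate CDR3 window, the quality-trim cutoff, and the
#' secondary-peak calling ratio. Every comparison against a threshold is
#' closed (>= / <=): a metric exactly at its threshold passes.
#'
#' @slot minRawLength minimum called-read length (bases).
#' @slot maxTrimStart the good-quality segment must start at or before this
#'   base (1-based).
#' @slot minTrimEnd the good-quality segment must extend at least to this
#'   base (1-based).
#' @slot minTrimmedMeanQuality minimum mean Phred score inside the trim
#'   segment.
#' @slot cdr3Start,cdr3End approximate CDR3 window in called-base
#'   coordinates, 1-based inclusive, clamped to the read.
#' @slot maxCdr3SecondaryPeaks maximum secondary-peak count tolerated
#'   inside the CDR3 window.
#' @slot secondaryPeakRatio a position is a secondary peak when the
#'   second-highest channel reaches this fraction of the highest, in (0, 1].
#' @slot trimCutoff error-probability cutoff of the modified-Mott trim,
#'   in (0, 1).
#'
#' @seealso [filterPreset()] for the shipped presets, [applyFilters()].
#' @export
setClass("FilterConfig",
  representation(
    minRawLength = "numeric",
    maxTrimStart = "numeric",
    minTrimEnd = "numeric",
    minTrimmedMeanQuality = "numeric",
    cdr3Start = "numeric",
    cdr3End = "numeric",
    maxCdr3SecondaryPeaks = "numeric",
    secondaryPeakRatio = "numeric",
    trimCutoff = "numeric"
  )
)

setValidity("FilterConfig", function(object) {
  msg <- character(0)
  one <- function(x) length(x) == 1L && is.finite(x)
  for (s in slotNames(object)) {
    if (!one(slot(object, s))) msg <- c(msg, paste0(s, " must be a single finite number"))
  }
  if (length(msg)) return(msg)
  if (object@minRawLength < 1) msg <- c(msg, "minRawLength must be >= 1")
  if (object@cdr3Start > object@cdr3End) msg <- c(msg, "cdr3Start must be <= cdr3End")
  if (object@secondaryPeakRatio <= 0 || object@secondaryPeakRatio > 1) {
    msg <- c(msg, "secondaryPeakRatio must be in (0, 1]")
  }
  if (object@trimCutoff <= 0 || object@trimCutoff >= 1) {
    msg <- c(msg, "trimCutoff must be in (0, 1)")
  }
  if (length(msg)) msg else TRUE
})

#' GateConfig: probe positivity gates on index-sort fluorescence
#'
#' Maps each probe to the fluorescence channel it was detected on and the
#' intensity at or above which an event counts as positive for the probe
#' (closed threshold). No compensation or transformation is applied: gates
#' act on the stored channel values.
#'
#' @slot probes character vector of unique probe names.
#' @slot channels character vector, channel gated for each probe.
#' @slot thresholds numeric vector of positivity thresholds.
#' @seealso [gateEvents()]
#' @export
setClass("GateConfig",
  representation(
    probes = "character",
    channels = "character",
    thresholds = "numeric"
  )
)

setValidity("GateConfig", function(object) {
  msg <- character(0)
  n <- length(object@probes)
  if (length(object@channels) != n || length(object@thresholds) != n) {
    msg <- c(msg, "probes, channels and thresholds must have equal length")
  }
  if (anyDuplicated(object@probes)) msg <- c(msg, "probe names must be unique")
  if (n && any(!is.finite(object@thresholds))) {
    msg <- c(msg, "thresholds must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GateConfig-class
#' @param probes,channels,thresholds parallel vectors defining one gate per
#'   probe.
#' @return a \code{GateConfig} object.
#' @examples
#' gateConfig(probes = c("PreF", "PostF"),
#'            channels = c("FITC-A", "APC-A"),
#'            thresholds = c(1500, 2000))
#' @export
gateConfig <- function(probes, channels, thresholds) {
  new("GateConfig", probes = as.character(probes),
      channels = as.character(channels), thresholds = as.numeric(thresholds))
}
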