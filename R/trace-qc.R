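# Per-chromatogram quality metrics: modified-Mott trim positions,
# secondary-peak counts, and the per-sequence summary consumed by
# filtering. Trim positions are used for filtering only; output sequences
# are never trimmed.

#' Good-quality trim positions by the modified-Mott algorithm
#'
#' Finds the contiguous segment of the read that maximises
#' \eqn{\sum_i (c - p_i)}, where \eqn{p_i = 10^{-q_i/10}} is the error
#' probability of base \eqn{i} and \eqn{c} the cutoff. Bases better than
#' the cutoff contribute positively, worse bases negatively, so the
#' maximal-scoring segment is the longest stretch the cutoff quality can
#' sustain. When no segment has a positive score the trim is undefined and
#' \code{c(0, 0)} is returned. Ties are broken toward the leftmost, then
#' shortest, maximal segment.
#'
#' The positions bound the good-quality region for filtering; they do not
#' cut the sequence.
#'
#' @param qualities integer/numeric vector of per-base Phred scores.
#' @param cutoff error-probability cutoff in (0, 1); the default 0.01
#'   corresponds to Phred 20.
#' @return integer vector \code{c(trim_start, trim_end)}, 1-based
#'   inclusive, or \code{c(0, 0)} when undefined.
#' @examples
#' computeTrim(c(10, 35, 40, 38, 8), cutoff = 0.01)
#' computeTrim(rep(2, 10), cutoff = 0.01)
#' @export
computeTrim <- function(qualities, cutoff = 0.01) {
  if (length(qualities) == 0L) stop("qualities must be non-empty")
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      cutoff <= 0 || cutoff >= 1) {
    stop("cutoff must be a single value in (0, 1)")
  }
  s <- cutoff - 10^(-as.numeric(qualities) / 10)
  n <- length(s)
  cs <- c(0, cumsum(s))
  best <- 0
  best_start <- 0L
  best_end <- 0L
  min_val <- 0      # minimal prefix sum seen so far
  min_idx <- 0L     # earliest index attaining it
  eps <- 1e-9 # ties resolved leftmost/shortest, robust to float noise
  for (j in seq_len(n)) {
    score <- cs[j + 1L] - min_val
    if (score > best + eps) {
      best <- score
      best_start <- min_idx + 1L
      best_end <- j
    }
    if (cs[j + 1L] < min_val - eps) {
      min_val <- cs[j + 1L]
      min_idx <- j
    }
  }
  if (best <= 0) return(c(0L, 0L))
  c(best_start, best_end)
}

#' Count secondary peaks in a chromatogram window
#'
#' A called-base position is a secondary-peak position when, at the call's
#' peak location, the second-highest of the four channel intensities
#' reaches at least \code{ratio} times the highest (and the highest is
#' positive). Such positions flag mixed template or poor trace quality —
#' in heavy-chain sequencing most critically inside the approximate CDR3
#' window. Intensities are taken from the stored analysed traces exactly
#' at the called peak index.
#'
#' @param chromatogram a [Chromatogram-class].
#' @param windowStart,windowEnd optional 1-based inclusive bounds in
#'   called-base coordinates; \code{NULL} means the whole read. Bounds are
#'   clamped to the read; a window entirely outside it yields 0 with a
#'   warning.
#' @param ratio secondary-to-primary intensity ratio in (0, 1] above which
#'   a position is called secondary (default 0.33).
#' @return integer count of secondary-peak positions in the window.
#' @export
countSecondaryPeaks <- function(chromatogram, windowStart = NULL,
                                windowEnd = NULL, ratio = 0.33) {
  validObject(chromatogram)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio <= 0 || ratio > 1) {
    stop("ratio must be a single value in (0, 1]")
  }
  n <- nchar(chromatogram@baseCalls)
  if (n == 0L) return(0L)
  ws <- if (is.null(windowStart)) 1L else as.integer(windowStart)
  we <- if (is.null(windowEnd)) n else as.integer(windowEnd)
  if (ws > we) stop("windowStart must be <= windowEnd")
  if (we < 1L || ws > n) {
    warning("secondary-peak window lies entirely outside the read")
    return(0L)
  }
  ws <- max(1L, ws)
  we <- min(n, we)
  locs <- chromatogram@peakLocations[ws:we] + 1L # 0-based -> row index
  sub <- chromatogram@traces[locs, , drop = FALSE]
  hi <- apply(sub, 1L, function(v) {
    v <- sort(v, decreasing = TRUE)
    c(v[1], v[2])
  })
  sum(hi[1, ] > 0 & hi[2, ] >= ratio * hi[1, ])
}

#' Summarise per-sequence quality
#'
#' Computes the full quality profile of one chromatogram: raw length and
#' mean Phred quality, modified-Mott trim positions (via [computeTrim()]
#' with the config's cutoff), mean quality and length inside the trim
#' segment, and secondary-peak counts inside the configured approximate
#' CDR3 window and over the whole read. When the trim is undefined the
#' trimmed quality and length are reported as 0.
#'
#' @param chromatogram a [Chromatogram-class].
#' @param config a [FilterConfig-class] supplying \code{trimCutoff},
#'   the CDR3 window and \code{secondaryPeakRatio}.
#' @return one-row data.frame with columns \code{sequence_id},
#'   \code{plate_id}, \code{well_id}, \code{source_path},
#'   \code{raw_length}, \code{raw_mean_quality}, \code{trim_start},
#'   \code{trim_end}, \code{trimmed_mean_quality}, \code{trimmed_length},
#'   \code{cdr3_secondary_peaks}, \code{total_secondary_peaks}.
#' @examples
#' cg <- makeChromatogram(length = 120, quality = "good", seed = 7)
#' summariseQuality(cg, filterPreset("bcr_default"))
#' @export
summariseQuality <- function(chromatogram, config = filterPreset("bcr_default")) {
  validObject(chromatogram)
  validObject(config)
  q <- chromatogram@qualities
  n <- length(q)
  if (n == 0L) {
    trim <- c(0L, 0L)
  } else {
    trim <- computeTrim(q, cutoff = config@trimCutoff)
  }
  trimmed_len <- if (trim[1] > 0L) trim[2] - trim[1] + 1L else 0L
  trimmed_mq <- if (trim[1] > 0L) mean(q[trim[1]:trim[2]]) else 0
  cdr3 <- if (n == 0L) 0L else suppressWarnings(
    countSecondaryPeaks(chromatogram, config@cdr3Start, config@cdr3End,
                        ratio = config@secondaryPeakRatio))
  tot <- if (n == 0L) 0L else countSecondaryPeaks(
    chromatogram, ratio = config@secondaryPeakRatio)
  seq_id <- paste0(chromatogram@plateId, "_", chromatogram@wellId)
  data.frame(
    sequence_id = seq_id,
    plate_id = chromatogram@plateId,
    well_id = chromatogram@wellId,
    source_path = chromatogram@sourcePath,
    raw_length = n,
    raw_mean_quality = if (n) mean(q) else 0,
    trim_start = trim[1],
    trim_end = trim[2],
    trimmed_mean_quality = trimmed_mq,
    trimmed_length = trimmed_len,
    cdr3_secondary_peaks = as.integer(cdr3),
    total_secondary_peaks = as.integer(tot),
    stringsAsFactors = FALSE
  )
}
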