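# Pass/fail filtering of quality metrics, shipped presets, the flat
# key-value config-file dialect, and technical-replicate deduplication.

.CONFIG_KEYS <- c(
  minRawLength = "min_raw_length",
  maxTrimStart = "max_trim_start",
  minTrimEnd = "min_trim_end",
  minTrimmedMeanQuality = "min_trimmed_mean_quality",
  cdr3Start = "cdr3_start",
  cdr3End = "cdr3_end",
  maxCdr3SecondaryPeaks = "max_cdr3_secondary_peaks",
  secondaryPeakRatio = "secondary_peak_ratio",
  trimCutoff = "trim_cutoff"
)

.PRESETS <- list(
  # Overridable defaults calibrated for full-length heavy-chain BCR
  # amplicons; the mouse-TCR preset shortens the length and trim-end
  # requirements for the shorter amplicons of common mouse TCR primers.
  bcr_default = c(min_raw_length = 400, max_trim_start = 50,
                  min_trim_end = 409, min_trimmed_mean_quality = 30,
                  cdr3_start = 100, cdr3_end = 150,
                  max_cdr3_secondary_peaks = 5,
                  secondary_peak_ratio = 0.33, trim_cutoff = 0.01),
  tcr_human = c(min_raw_length = 400, max_trim_start = 50,
                min_trim_end = 409, min_trimmed_mean_quality = 30,
                cdr3_start = 100, cdr3_end = 150,
                max_cdr3_secondary_peaks = 5,
                secondary_peak_ratio = 0.33, trim_cutoff = 0.01),
  tcr_mouse = c(min_raw_length = 200, max_trim_start = 50,
                min_trim_end = 250, min_trimmed_mean_quality = 30,
                cdr3_start = 100, cdr3_end = 150,
                max_cdr3_secondary_peaks = 5,
                secondary_peak_ratio = 0.33, trim_cutoff = 0.01)
)

.config_from_values <- function(v) {
  new("FilterConfig",
      minRawLength = unname(v[["min_raw_length"]]),
      maxTrimStart = unname(v[["max_trim_start"]]),
      minTrimEnd = unname(v[["min_trim_end"]]),
      minTrimmedMeanQuality = unname(v[["min_trimmed_mean_quality"]]),
      cdr3Start = unname(v[["cdr3_start"]]),
      cdr3End = unname(v[["cdr3_end"]]),
      maxCdr3SecondaryPeaks = unname(v[["max_cdr3_secondary_peaks"]]),
      secondaryPeakRatio = unname(v[["secondary_peak_ratio"]]),
      trimCutoff = unname(v[["trim_cutoff"]]))
}

#' Shipped filter presets
#'
#' Returns one of the shipped [FilterConfig-class] presets, optionally
#' with individual thresholds overridden. \code{"bcr_default"} targets
#' full-length heavy-chain BCR amplicons; \code{"tcr_human"} starts from
#' the same values (human TCR amplicons are of comparable length);
#' \code{"tcr_mouse"} lowers the length filter to 200 and the trimming
#' end position to 250 for the shorter amplicons of common mouse TCR
#' primer sets. Every threshold is a plain number and fully overridable.
#'
#' @param name preset name: "bcr_default", "tcr_human" or "tcr_mouse".
#' @param ... named overrides in config-key form, e.g.
#'   \code{min_raw_length = 350} or \code{cdr3_start = 90}.
#' @return a [FilterConfig-class].
#' @examples
#' filterPreset("tcr_mouse")
#' filterPreset("bcr_default", cdr3_start = 90, cdr3_end = 140)
#' @export
filterPreset <- function(name = c("bcr_default", "tcr_human", "tcr_mouse"),
                         ...) {
  name <- match.arg(name)
  v <- .PRESETS[[name]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(v))
    if (length(bad)) stop("unknown filter key(s): ", paste(bad, collapse = ", "))
    v[names(dots)] <- as.numeric(unlist(dots))
  }
  .config_from_values(v)
}

#' Read a filter config file
#'
#' Parses the flat key-value config dialect: \code{[preset_name]} section
#' headers followed by \code{key = value} lines (keys as in
#' [filterPreset()]; \code{#} comments allowed). Keys missing from the
#' file fall back to the \code{"bcr_default"} preset values.
#'
#' @param path config file path.
#' @param preset section to read; defaults to the first section in the
#'   file.
#' @return a [FilterConfig-class].
#' @seealso [writeFilterConfig()]
#' @export
readFilterConfig <- function(path, preset = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- NA_character_
  values <- list()
  for (ln in lines) {
    if (grepl("^\\[.+\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      values[[section]] <- c()
    } else if (grepl("=", ln, fixed = TRUE)) {
      if (is.na(section)) stop("config line outside any [section]: ", ln)
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      key <- trimws(kv[1])
      values[[section]][key] <- as.numeric(trimws(paste(kv[-1], collapse = "=")))
    }
  }
  if (length(values) == 0L) stop("no preset sections in ", path)
  if (is.null(preset)) preset <- names(values)[1]
  if (!preset %in% names(values)) {
    stop("preset '", preset, "' not found in ", path)
  }
  v <- .PRESETS$bcr_default
  got <- values[[preset]]
  unknown <- setdiff(names(got), names(v))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  v[names(got)] <- got
  .config_from_values(v)
}

#' Write a filter config file
#'
#' Emits a [FilterConfig-class] in the same dialect [readFilterConfig()]
#' consumes, as one named section of \code{key = value} lines.
#'
#' @param config a [FilterConfig-class].
#' @param path output path.
#' @param name section name (default "derived").
#' @return the path, invisibly.
#' @export
writeFilterConfig <- function(config, path, name = "derived") {
  validObject(config)
  lines <- c(sprintf("[%s]", name),
             vapply(names(.CONFIG_KEYS), function(s) {
               sprintf("%s = %.10g", .CONFIG_KEYS[[s]], slot(config, s))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Apply quality filters to per-sequence metrics
#'
#' Checks every filter criterion independently against a metrics table
#' (rows as produced by [summariseQuality()]) and names each violated
#' criterion. All comparisons are closed: a metric exactly at its
#' threshold passes. An undefined trim (\code{trim_start == 0}) fails both
#' trim criteria — this is how empty wells are removed. Tightening any
#' single threshold can never turn a failing sequence into a passing one.
#'
#' @param metrics data.frame of quality metrics, one row per sequence.
#' @param config a [FilterConfig-class].
#' @return data.frame with columns \code{sequence_id}, \code{passed}
#'   (logical) and \code{failed_criteria} (semicolon-joined names, ""
#'   when passed).
#' @examples
#' cg <- makeChromatogram(length = 450, quality = "good", seed = 3)
#' m <- summariseQuality(cg, filterPreset("bcr_default"))
#' applyFilters(m, filterPreset("bcr_default"))
#' @export
applyFilters <- function(metrics, config) {
  validObject(config)
  fails <- lapply(seq_len(nrow(metrics)), function(i) {
    m <- metrics[i, ]
    f <- character(0)
    if (m$raw_length < config@minRawLength) f <- c(f, "min_raw_length")
    trim_ok <- m$trim_start >= 1
    if (!trim_ok || m$trim_start > config@maxTrimStart) {
      f <- c(f, "max_trim_start")
    }
    if (!trim_ok || m$trim_end < config@minTrimEnd) f <- c(f, "min_trim_end")
    if (m$trimmed_mean_quality < config@minTrimmedMeanQuality) {
      f <- c(f, "min_trimmed_mean_quality")
    }
    if (m$cdr3_secondary_peaks > config@maxCdr3SecondaryPeaks) {
      f <- c(f, "max_cdr3_secondary_peaks")
    }
    f
  })
  data.frame(
    sequence_id = metrics$sequence_id,
    passed = lengths(fails) == 0L,
    failed_criteria = vapply(fails, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Deduplicate technical replicates
#'
#' Keeps at most one sequence per (plate, well). The default
#' \code{"best-quality"} policy retains the replicate with the highest
#' trimmed mean quality, breaking ties by lexicographically smallest
#' source file name; removed replicates are returned in an audit table.
#'
#' @param metrics metrics data.frame (must carry \code{plate_id},
#'   \code{well_id}, \code{trimmed_mean_quality}, \code{source_path}).
#' @param policy deduplication policy; only \code{"best-quality"} is
#'   defined.
#' @return list with \code{kept} (deduplicated metrics, input order
#'   preserved) and \code{removed} (audit table of dropped replicates
#'   with a \code{removed_reason} column).
#' @export
dedupeReplicates <- function(metrics, policy = "best-quality") {
  if (!identical(policy, "best-quality")) {
    stop("unknown deduplication policy: ", policy)
  }
  if (nrow(metrics) == 0L) {
    return(list(kept = metrics, removed = metrics))
  }
  key <- paste(metrics$plate_id, metrics$well_id, sep = "\r")
  keep <- logical(nrow(metrics))
  for (k in unique(key)) {
    idx <- which(key == k)
    best <- idx[order(-metrics$trimmed_mean_quality[idx],
                      basename(metrics$source_path[idx]))][1]
    keep[best] <- TRUE
  }
  removed <- metrics[!keep, , drop = FALSE]
  if (nrow(removed)) removed$removed_reason <- "technical replicate"
  list(kept = metrics[keep, , drop = FALSE], removed = removed)
}
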