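# FCS 3.0/3.1 reader and 3.1 writer for index-sort files. HEADER with
# ASCII offsets, delimited TEXT segment, float or integer DATA. Well
# coordinates travel in the BD-style "INDEX SORTING LOCATIONS_n" keyword
# family as 0-based "row,col" pairs.

.INDEX_KEY_PREFIX <- "INDEX SORTING LOCATIONS_"
.INDEX_CHUNK <- 200L # characters per numbered keyword, BD-style splitting

.fcs_read_text <- function(bytes, begin, end) {
  txt <- rawToChar(bytes[(begin + 1L):(end + 1L)])
  delim <- substr(txt, 1L, 1L)
  body <- substr(txt, 2L, nchar(txt))
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  # a trailing delimiter leaves a final "" which strsplit drops; pairs only
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  idx <- seq(1L, length(parts), by = 2L)
  stats::setNames(as.list(parts[idx + 1L]), trimws(parts[idx]))
}

#' Read index-sort events from an FCS file
#'
#' Parses an FCS 3.0 or 3.1 file written by an index-sorting cytometer into
#' one event per sorted cell. Channel names come from the \code{$PnN}
#' keywords (falling back to \code{$PnS}); well coordinates are decoded
#' from the BD-dialect \code{INDEX SORTING LOCATIONS_n} keyword family
#' (0-based "row,col" pairs, so "0,0" is well A01). Both \code{$DATATYPE}
#' F (IEEE float) and I (unsigned integer with \code{$PnB}/\code{$PnR})
#' data are supported.
#'
#' @param path path to an ".fcs" file.
#' @return a data.frame with one row per event, ordered as stored:
#'   columns \code{plate_id} (file stem), \code{well_id} (canonical), then
#'   one numeric column per fluorescence channel.
#' @seealso [writeFCS()], [gateEvents()]
#' @export
readFCSIndex <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 58L) stop("FCS file truncated: ", path)
  version <- rawToChar(bytes[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version '", version, "' in ", path)
  }
  off <- function(i) {
    as.integer(trimws(rawToChar(bytes[(10L + 8L * (i - 1L) + 1L):(10L + 8L * i)])))
  }
  text_begin <- off(1); text_end <- off(2)
  kw <- .fcs_read_text(bytes, text_begin, text_end)
  need <- function(k) {
    v <- kw[[k]]
    if (is.null(v)) stop("FCS keyword ", k, " missing in ", path)
    v
  }
  npar <- as.integer(need("$PAR"))
  ntot <- as.integer(need("$TOT"))
  dtype <- need("$DATATYPE")
  byteord <- gsub("\\s", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little" else "big"

  data_begin <- off(3); data_end <- off(4)
  if (data_begin == 0L) data_begin <- as.integer(need("$BEGINDATA"))
  if (data_end == 0L) data_end <- as.integer(need("$ENDDATA"))

  chan <- vapply(seq_len(npar), function(p) {
    v <- kw[[sprintf("$P%dN", p)]]
    if (is.null(v)) v <- kw[[sprintf("$P%dS", p)]]
    if (is.null(v)) sprintf("P%d", p) else v
  }, character(1))
  if (anyDuplicated(chan)) stop("duplicate channel names in ", path)

  if (ntot * npar == 0L) {
    vals <- numeric(0)
    nbytes <- 0L
    payload <- raw(0)
  } else {
    nbytes <- data_end - data_begin + 1L
    payload <- bytes[(data_begin + 1L):(data_end + 1L)]
  }
  if (ntot * npar == 0L) {
  } else if (dtype == "F") {
    if (nbytes < 4L * npar * ntot) {
      stop("FCS DATA segment shorter than $TOT x $PAR in ", path)
    }
    vals <- readBin(payload, "numeric", n = npar * ntot, size = 4L,
                    endian = endian)
  } else if (dtype == "I") {
    bits <- vapply(seq_len(npar), function(p)
      as.integer(need(sprintf("$P%dB", p))), integer(1))
    if (length(unique(bits)) != 1L) {
      stop("mixed $PnB widths not supported in ", path)
    }
    size <- bits[1] %/% 8L
    if (nbytes < size * npar * ntot) {
      stop("FCS DATA segment shorter than $TOT x $PAR in ", path)
    }
    vals <- readBin(payload, "integer", n = npar * ntot, size = size,
                    signed = size > 2L, endian = endian)
    ranges <- vapply(seq_len(npar), function(p)
      as.numeric(need(sprintf("$P%dR", p))), numeric(1))
    vals <- matrix(vals, ncol = npar, byrow = TRUE)
    for (p in seq_len(npar)) {
      r <- ranges[p]
      if (r > 0 && abs(log2(r) - round(log2(r))) < 1e-9) {
        vals[, p] <- vals[, p] %% r
      }
    }
    vals <- as.numeric(t(vals))
  } else {
    stop("unsupported $DATATYPE '", dtype, "' in ", path)
  }
  mat <- matrix(vals, ncol = npar, byrow = TRUE,
                dimnames = list(NULL, chan))

  idx_keys <- grep(paste0("^", .INDEX_KEY_PREFIX, "[0-9]+$"), names(kw),
                   value = TRUE)
  if (ntot == 0L) {
    wells <- character(0)
  } else {
    if (length(idx_keys) == 0L) {
      stop("no index data: FCS file carries no '", .INDEX_KEY_PREFIX,
           "n' keywords: ", path)
    }
    ord <- order(as.integer(sub(paste0("^", .INDEX_KEY_PREFIX), "", idx_keys)))
    loc_str <- paste0(unlist(kw[idx_keys[ord]]), collapse = "")
    loc_str <- sub(";+$", "", loc_str)
    pairs <- strsplit(loc_str, ";", fixed = TRUE)[[1]]
    if (length(pairs) != ntot) {
      stop("index-sort locations (", length(pairs),
           ") disagree with $TOT (", ntot, ") in ", path)
    }
    rc <- do.call(rbind, lapply(strsplit(pairs, ",", fixed = TRUE), as.integer))
    wells <- sprintf("%s%02d", LETTERS[rc[, 1] + 1L], rc[, 2] + 1L)
    bad <- is.na(canonicalWell(wells))
    if (any(bad)) stop("index-sort coordinates outside plate range in ", path)
  }

  out <- data.frame(
    plate_id = rep(tools::file_path_sans_ext(basename(path)), ntot),
    well_id = wells, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat, optional = TRUE))
}

#' Write index-sort events as an FCS 3.1 file
#'
#' Serializes per-well events into a minimal valid FCS 3.1 file: ASCII
#' HEADER offsets, TEXT segment with \code{$PnN}/\code{$PnB}/\code{$PnE}/
#' \code{$PnR}, little-endian float32 DATA (\code{$DATATYPE} F), and the
#' BD-dialect index-sorting location keywords decoded by [readFCSIndex()].
#'
#' @param events data.frame with a \code{well_id} column (canonical labels)
#'   and one numeric column per channel in \code{channelNames}.
#' @param channelNames channels to store, in order; every one must be a
#'   column of \code{events}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFCS <- function(events, channelNames, path) {
  if (!all(channelNames %in% names(events))) {
    stop("events lack channel column(s): ",
         paste(setdiff(channelNames, names(events)), collapse = ", "))
  }
  ntot <- nrow(events)
  if (ntot > 0L) {
    wells <- canonicalWell(events$well_id)
    if (any(is.na(wells))) stop("invalid well_id in events")
    row0 <- match(substr(wells, 1L, 1L), LETTERS) - 1L
    col0 <- as.integer(substr(wells, 2L, 3L)) - 1L
    locs <- paste0(row0, ",", col0, ";", collapse = "")
  } else {
    locs <- ""
  }
  npar <- length(channelNames)

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = "%BD%", "$ENDDATA" = "%ED%",
    "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$PAR" = as.character(npar), "$TOT" = as.character(ntot)
  )
  for (p in seq_len(npar)) {
    kw[sprintf("$P%dN", p)] <- channelNames[p]
    kw[sprintf("$P%dB", p)] <- "32"
    kw[sprintf("$P%dE", p)] <- "0,0"
    kw[sprintf("$P%dR", p)] <- "262144"
  }
  if (nzchar(locs)) {
    chunks <- substring(locs, seq(1L, nchar(locs), by = .INDEX_CHUNK),
                        pmin(seq(1L, nchar(locs), by = .INDEX_CHUNK) +
                               .INDEX_CHUNK - 1L, nchar(locs)))
    for (i in seq_along(chunks)) {
      kw[paste0(.INDEX_KEY_PREFIX, i)] <- chunks[i]
    }
  }

  delim <- "/"
  text_body <- paste0(delim, paste0(names(kw), delim, unname(kw), delim,
                                    collapse = ""))
  text_begin <- 64L
  # data offsets use fixed 10-digit fields so the TEXT length is stable
  text_len <- nchar(text_body) + 2L * (10L - 4L) # %BD%/%ED% grow to 10 chars
  data_begin <- text_begin + text_len
  data_end <- if (ntot * npar > 0L) data_begin + 4L * npar * ntot - 1L else data_begin
  text_body <- sub("%BD%", sprintf("%010d", data_begin), text_body, fixed = TRUE)
  text_body <- sub("%ED%", sprintf("%010d", data_end), text_body, fixed = TRUE)
  text_end <- text_begin + nchar(text_body) - 1L

  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", text_begin, text_end,
                    data_begin, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(strrep(" ", text_begin - 58L)), con)
  writeBin(charToRaw(text_body), con)
  if (ntot * npar > 0L) {
    vals <- as.numeric(t(as.matrix(events[, channelNames, drop = FALSE])))
    writeBin(vals, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Gate index-sort events for probe positivity
#'
#' Labels every event positive or negative for each configured probe. An
#' event is positive for a probe when its value on the gated channel is at
#' or above the probe's MFI threshold (closed threshold: exactly-at-gate is
#' positive). Events can be positive for several probes at once, as with
#' cells binding an antigen in two conformations. Gating is monotone:
#' raising a threshold never increases the positive count.
#'
#' @param events event data.frame from [readFCSIndex()].
#' @param gates a [GateConfig-class].
#' @return logical matrix, one row per event and one column per probe.
#' @export
gateEvents <- function(events, gates) {
  validObject(gates)
  missing_ch <- setdiff(gates@channels, names(events))
  if (length(missing_ch)) {
    stop("gated channel(s) absent from events: ",
         paste(missing_ch, collapse = ", "))
  }
  out <- vapply(seq_along(gates@probes), function(i) {
    events[[gates@channels[i]]] >= gates@thresholds[i]
  }, logical(nrow(events)))
  out <- matrix(out, nrow = nrow(events),
                dimnames = list(NULL, gates@probes))
  out
}

#' Plot an index-sort fluorescence density scatter
#'
#' Writes a two-channel density scatter of index-sort events, in the style
#' of conventional flow-cytometry density plots, with any configured gate
#' thresholds overlaid as dashed lines.
#'
#' @param events event data.frame from [readFCSIndex()].
#' @param channelX,channelY channels to plot.
#' @param gates optional [GateConfig-class]; thresholds on the two plotted
#'   channels are drawn as gate lines.
#' @param outPath output PNG path.
#' @return invisibly, a list describing the plot (file, axis labels and
#'   the gate lines drawn), for programmatic inspection.
#' @export
fcsDensityPlot <- function(events, channelX, channelY, gates = NULL,
                           outPath) {
  if (nrow(events) == 0L) stop("no events to plot")
  for (ch in c(channelX, channelY)) {
    if (!ch %in% names(events)) stop("channel absent from events: ", ch)
  }
  vlines <- hlines <- numeric(0)
  if (!is.null(gates)) {
    vlines <- gates@thresholds[gates@channels == channelX]
    hlines <- gates@thresholds[gates@channels == channelY]
  }
  grDevices::png(outPath, width = 720, height = 720, res = 110)
  on.exit(grDevices::dev.off())
  x <- events[[channelX]]; y <- events[[channelY]]
  if (nrow(events) >= 10L) {
    graphics::smoothScatter(x, y, xlab = channelX, ylab = channelY,
                            main = unique(events$plate_id)[1])
    graphics::points(x, y, pch = 16, cex = 0.35,
                     col = grDevices::adjustcolor("black", 0.5))
  } else {
    graphics::plot(x, y, xlab = channelX, ylab = channelY, pch = 16)
  }
  if (length(vlines)) graphics::abline(v = vlines, lty = 2, col = "red3")
  if (length(hlines)) graphics::abline(h = hlines, lty = 2, col = "red3")
  invisible(list(file = outPath, xlab = channelX, ylab = channelY,
                 gate_x = vlines, gate_y = hlines))
}
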