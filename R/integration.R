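# Per-well integration of sequence QC and index-sort fluorescence, and
# all file outputs: FASTA of passing sequences (never trimmed), summary
# table, QC report, CDR3 electropherograms.

.SUMMARY_METRIC_COLS <- c("sequence_id", "source_path", "raw_length",
  "raw_mean_quality", "trim_start", "trim_end", "trimmed_mean_quality",
  "trimmed_length", "cdr3_secondary_peaks", "total_secondary_peaks")

#' Join sequence metrics with index-sort events per well
#'
#' Full outer join on (plate, well): every metrics row and every event
#' appears in exactly one well record. Wells sequenced but not sorted (or
#' the reverse) are kept with the absent side empty — neither input is
#' mandatory — and counted in the unmatched report. The cytometry side
#' must be unique per well: index sorting deposits one cell per well, so
#' a duplicate (plate, well) event is an error.
#'
#' @param metrics metrics data.frame (may carry verdict columns
#'   \code{passed}/\code{failed_criteria} from [applyFilters()]).
#' @param events event data.frame from [readFCSIndex()] (may carry probe
#'   label columns from [gateEvents()]); may be \code{NULL}.
#' @return list with \code{records} (one row per well; \code{has_metrics}
#'   and \code{has_event} flag the populated sides) and \code{unmatched}
#'   (counts: \code{sequence_only}, \code{index_only}).
#' @export
matchWells <- function(metrics, events = NULL) {
  if (is.null(events)) {
    events <- data.frame(plate_id = character(0), well_id = character(0),
                         stringsAsFactors = FALSE)
  }
  ekey <- paste(events$plate_id, events$well_id, sep = "\r")
  if (anyDuplicated(ekey)) {
    stop("duplicate (plate, well) on the cytometry side: ",
         paste(unique(gsub("\r", "/", ekey[duplicated(ekey)])),
               collapse = ", "))
  }
  m <- metrics
  m$has_metrics <- rep(TRUE, nrow(m))
  e <- events
  e$has_event <- rep(TRUE, nrow(e))
  records <- merge(m, e, by = c("plate_id", "well_id"), all = TRUE,
                   sort = TRUE)
  records$has_metrics[is.na(records$has_metrics)] <- FALSE
  records$has_event[is.na(records$has_event)] <- FALSE
  list(records = records,
       unmatched = list(
         sequence_only = sum(records$has_metrics & !records$has_event),
         index_only = sum(!records$has_metrics & records$has_event)))
}

#' Write passing sequences as FASTA
#'
#' One record per passing well, headed \code{plate<sep>well}. Sequences
#' are the full untrimmed base calls: trim positions inform filtering
#' only and never cut the output. Failing or sequence-absent wells are
#' excluded; zero passing wells yield a valid empty FASTA.
#'
#' @param records well records from [matchWells()] (need \code{passed}).
#' @param chromatograms named list of [Chromatogram-class] objects keyed
#'   by \code{sequence_id}; every passing record must have one.
#' @param outPath output FASTA path.
#' @param sep separator between plate and well in headers.
#' @return invisibly, the headers written.
#' @export
writeFasta <- function(records, chromatograms, outPath, sep = "_") {
  pass <- records[records$has_metrics & records$passed %in% TRUE, ,
                  drop = FALSE]
  headers <- character(0)
  seqs <- character(0)
  for (i in seq_len(nrow(pass))) {
    id <- pass$sequence_id[i]
    cg <- chromatograms[[id]]
    if (is.null(cg)) stop("no chromatogram for passing sequence ", id)
    headers <- c(headers, paste0(pass$plate_id[i], sep, pass$well_id[i]))
    seqs <- c(seqs, baseCalls(cg))
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- headers
  Biostrings::writeXStringSet(dna, outPath)
  invisible(headers)
}

#' Write the per-well summary table
#'
#' One tab-separated row per well record: identity, every quality metric,
#' the filter verdict with the violated criteria semicolon-joined, and
#' the index-sort channel values and probe labels where present. Sides
#' absent from a well are left as empty cells. Column order is stable
#' across runs.
#'
#' @param records well records from [matchWells()].
#' @param outPath output TSV path.
#' @return invisibly, the data.frame written.
#' @export
writeSummaryTable <- function(records, outPath) {
  lead <- c("plate_id", "well_id",
            intersect(.SUMMARY_METRIC_COLS, names(records)),
            intersect(c("passed", "failed_criteria"), names(records)),
            intersect(c("has_metrics", "has_event"), names(records)))
  rest <- setdiff(names(records), lead)
  out <- records[, c(lead, rest), drop = FALSE]
  out <- out[order(out$plate_id, out$well_id), , drop = FALSE]
  utils::write.table(out, outPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(out)
}

#' Plot a CDR3 electropherogram
#'
#' Renders the four dye-channel traces across the approximate CDR3
#' window (padded by five bases on each side), annotates the called
#' bases, and highlights the positions called as secondary peaks. Meant
#' as the manual-inspection aid for sequences failing the CDR3
#' secondary-peak criterion.
#'
#' @param chromatogram a [Chromatogram-class].
#' @param cdr3Start,cdr3End CDR3 window in called-base coordinates; the
#'   window must intersect the read.
#' @param outPath output PNG path.
#' @param ratio secondary-peak calling ratio used for highlighting.
#' @return invisibly, a list: \code{file}, \code{window} (clamped),
#'   \code{highlighted} (base positions marked as secondary peaks).
#' @export
plotCdr3Electropherogram <- function(chromatogram, cdr3Start, cdr3End,
                                     outPath, ratio = 0.33) {
  validObject(chromatogram)
  n <- nchar(chromatogram@baseCalls)
  if (cdr3Start > cdr3End) stop("cdr3Start must be <= cdr3End")
  if (cdr3End < 1L || cdr3Start > n) {
    stop("CDR3 window lies outside the read")
  }
  ws <- max(1L, as.integer(cdr3Start))
  we <- min(n, as.integer(cdr3End))
  pad_s <- max(1L, ws - 5L)
  pad_e <- min(n, we + 5L)

  locs <- chromatogram@peakLocations
  bases <- strsplit(chromatogram@baseCalls, "")[[1]]
  x0 <- locs[pad_s]
  x1 <- locs[pad_e]
  idx <- (x0:x1) + 1L
  tr <- chromatogram@traces[idx, , drop = FALSE]

  # per-position secondary calls inside the (unpadded) window
  hl <- integer(0)
  for (b in ws:we) {
    v <- sort(chromatogram@traces[locs[b] + 1L, ], decreasing = TRUE)
    if (v[1] > 0 && v[2] >= ratio * v[1]) hl <- c(hl, b)
  }

  cols <- c(G = "black", A = "forestgreen", T = "red3", C = "blue3")
  grDevices::png(outPath, width = 1100, height = 420, res = 110)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::matplot(x0:x1, tr, type = "l", lty = 1,
                    col = cols[colnames(tr)], xlab = "trace sample",
                    ylab = "intensity",
                    main = sprintf("%s %s: CDR3 window %d-%d",
                                   chromatogram@plateId,
                                   chromatogram@wellId, ws, we))
  if (length(hl)) {
    graphics::abline(v = locs[hl], col = "orange", lwd = 2, lty = 3)
  }
  ymax <- max(tr, 1)
  graphics::text(locs[pad_s:pad_e], ymax * 1.02, bases[pad_s:pad_e],
                 cex = 0.6, xpd = NA)
  graphics::legend("topright", legend = names(cols), col = cols, lty = 1,
                   cex = 0.7, bty = "n")
  invisible(list(file = outPath, window = c(ws, we), highlighted = hl))
}

.fmt_num <- function(x) formatC(x, format = "g", digits = 6)

.report_sections <- function(records, config) {
  has_m <- records$has_metrics
  n_pass <- sum(records$passed %in% TRUE)
  n_fail <- sum(has_m) - n_pass
  overall <- list(
    n_records = nrow(records),
    n_with_sequence = sum(has_m),
    n_with_event = sum(records$has_event),
    n_pass = n_pass, n_fail = n_fail,
    pass_rate = if (sum(has_m)) n_pass / sum(has_m) else NA_real_)

  metric_cols <- intersect(c("raw_length", "raw_mean_quality",
    "trim_start", "trim_end", "trimmed_mean_quality", "trimmed_length",
    "cdr3_secondary_peaks", "total_secondary_peaks"), names(records))
  if (!any(has_m)) metric_cols <- character(0)
  dist <- do.call(rbind, lapply(metric_cols, function(mc) {
    v <- records[[mc]][has_m]
    data.frame(metric = mc, mean = mean(v), sd = stats::sd(v),
               min = min(v), median = stats::median(v), max = max(v),
               stringsAsFactors = FALSE)
  }))

  thr <- data.frame(
    key = unname(.CONFIG_KEYS),
    value = vapply(names(.CONFIG_KEYS), function(s)
      slot(config, s), numeric(1)),
    stringsAsFactors = FALSE)

  plates <- sort(unique(records$plate_id))
  per_plate <- lapply(plates, function(p) {
    r <- records[records$plate_id == p, , drop = FALSE]
    np <- sum(r$passed %in% TRUE)
    list(plate = p, n = nrow(r), n_with_sequence = sum(r$has_metrics),
         n_pass = np,
         pass_rate = if (sum(r$has_metrics)) np / sum(r$has_metrics) else NA_real_)
  })
  list(overall = overall, dist = dist, thresholds = thr,
       per_plate = per_plate)
}

.md_table <- function(df) {
  fmt <- function(v) if (is.numeric(v)) .fmt_num(v) else as.character(v)
  body <- apply(vapply(df, fmt, character(nrow(df))), 1L, paste,
                collapse = " | ")
  c(paste("|", paste(names(df), collapse = " | "), "|"),
    paste("|", paste(rep("---", ncol(df)), collapse = " | "), "|"),
    paste("|", body, "|"))
}

.html_table <- function(df) {
  fmt <- function(v) if (is.numeric(v)) .fmt_num(v) else as.character(v)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  rows <- apply(cells, 1L, function(r)
    paste0("<tr><td>", paste(r, collapse = "</td><td>"), "</td></tr>"))
  paste0("<table><tr><th>",
         paste(names(df), collapse = "</th><th>"), "</th></tr>",
         paste(rows, collapse = ""), "</table>")
}

#' Write the QC report
#'
#' Produces the self-contained quality-control report: overall counts and
#' pass rate, per-metric distribution summaries, the exact filter
#' thresholds applied, and one section per plate. Reports embed no
#' timestamps, so identical inputs yield byte-identical reports. Both a
#' static HTML report and a plain-markdown fallback are written from the
#' same computed content.
#'
#' @param records well records from [matchWells()].
#' @param config the [FilterConfig-class] that produced the verdicts.
#' @param outPath output path; ".html" and ".md" siblings are written
#'   (whichever extension is given, the other is added).
#' @param title report title.
#' @return invisibly, a list: \code{html}, \code{markdown} (paths) and
#'   \code{sections} (the computed content).
#' @export
qualityReport <- function(records, config, outPath,
                          title = "Sequencing quality report") {
  sec <- .report_sections(records, config)
  stem <- sub("\\.(html|md)$", "", outPath)
  md_path <- paste0(stem, ".md")
  html_path <- paste0(stem, ".html")

  ov <- sec$overall
  ov_df <- data.frame(
    quantity = c("well records", "with sequence", "with index event",
                 "passed", "failed", "pass rate"),
    value = c(ov$n_records, ov$n_with_sequence, ov$n_with_event,
              ov$n_pass, ov$n_fail, round(ov$pass_rate, 4)),
    stringsAsFactors = FALSE)

  md <- c(paste("#", title), "",
          "## Overall", "", .md_table(ov_df), "",
          "## Filter thresholds", "", .md_table(sec$thresholds), "")
  if (!is.null(sec$dist) && nrow(sec$dist)) {
    md <- c(md, "## Metric distributions", "", .md_table(sec$dist), "")
  }
  for (pp in sec$per_plate) {
    pp_df <- data.frame(
      quantity = c("wells", "with sequence", "passed", "pass rate"),
      value = c(pp$n, pp$n_with_sequence, pp$n_pass,
                round(pp$pass_rate, 4)),
      stringsAsFactors = FALSE)
    md <- c(md, paste("## Plate", pp$plate), "", .md_table(pp_df), "")
  }
  writeLines(md, md_path)

  html <- c("<!DOCTYPE html><html><head><meta charset='utf-8'>",
    sprintf("<title>%s</title>", title),
    "<style>body{font-family:sans-serif;margin:2em;}table{border-collapse:collapse;margin:0.5em 0;}td,th{border:1px solid #999;padding:2px 8px;text-align:left;}</style>",
    "</head><body>",
    sprintf("<h1>%s</h1>", title),
    "<h2>Overall</h2>", .html_table(ov_df),
    "<h2>Filter thresholds</h2>", .html_table(sec$thresholds))
  if (!is.null(sec$dist) && nrow(sec$dist)) {
    html <- c(html, "<h2>Metric distributions</h2>", .html_table(sec$dist))
  }
  for (pp in sec$per_plate) {
    pp_df <- data.frame(
      quantity = c("wells", "with sequence", "passed", "pass rate"),
      value = c(pp$n, pp$n_with_sequence, pp$n_pass,
                round(pp$pass_rate, 4)),
      stringsAsFactors = FALSE)
    html <- c(html, sprintf("<h2>Plate %s</h2>", pp$plate),
              .html_table(pp_df))
  }
  html <- c(html, "</body></html>")
  writeLines(html, html_path)
  invisible(list(html = html_path, markdown = md_path, sections = sec))
}
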