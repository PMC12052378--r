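# End-to-end workflow: discover -> read -> summarise (parallel) ->
# dedupe -> filter -> match -> gate -> write the full output set.

#' Run the full QC workflow on a plate tree
#'
#' Discovers ".ab1" traces under \code{inputDir} (one folder per plate),
#' computes per-sequence quality metrics in parallel, deduplicates
#' technical replicates, applies the filter config, joins the result with
#' index-sort events from FCS files whose names match plate folders, and
#' writes the complete output set to \code{outDir}:
#' \itemize{
#'   \item \code{sequences.fasta} — passing sequences, untrimmed;
#'   \item \code{summary.tsv} — one row per well;
#'   \item \code{report.html} / \code{report.md} — overall and per-plate
#'     QC report;
#'   \item \code{rejects.tsv} — discovery rejects and unreadable files;
#'   \item \code{electropherograms/} — CDR3 trace plots for sequences
#'     failing the CDR3 secondary-peak criterion;
#'   \item \code{density_plots/} — per-plate two-channel fluorescence
#'     density plots (when index data and gates are available).
#' }
#' Per-file read failures are logged and skipped, ending up in the
#' rejects table rather than aborting the run. Results are independent of
#' \code{threads}: work is split per chromatogram with deterministic
#' result ordering, so serial and parallel runs write byte-identical
#' outputs.
#'
#' @param inputDir root directory of plate folders with ".ab1" files.
#' @param outDir output directory (must differ from \code{inputDir});
#'   created if needed.
#' @param config a [FilterConfig-class] or preset name for
#'   [filterPreset()].
#' @param fcsDir directory searched recursively for "<plate>.fcs" files;
#'   defaults to \code{inputDir}. \code{NA} disables index integration.
#' @param gates optional [GateConfig-class] for probe positivity labels
#'   and density-plot gate lines.
#' @param threads worker processes for trace reading and QC (>= 1).
#' @param quiet suppress progress messages.
#' @return invisibly, a list: \code{records}, \code{metrics},
#'   \code{unmatched}, \code{outputs} (named file paths), \code{rejects}.
#' @export
runQC <- function(inputDir, outDir, config = "bcr_default", fcsDir = NULL,
                  gates = NULL, threads = 1L, quiet = FALSE) {
  if (is.character(config)) config <- filterPreset(config)
  validObject(config)
  threads <- max(1L, as.integer(threads))
  if (!dir.exists(inputDir)) stop("input directory not found: ", inputDir)
  if (normalizePath(inputDir) ==
      normalizePath(outDir, mustWork = FALSE)) {
    stop("output directory must differ from input directory")
  }
  say <- function(...) if (!quiet) message(...)

  disc <- discoverInputs(inputDir)
  if (nrow(disc$files) == 0L) stop("no .ab1 files found under ", inputDir)
  say("discovered ", nrow(disc$files), " trace file(s), ",
      nrow(disc$rejects), " reject(s)")

  apply_fun <- if (threads > 1L) {
    function(x, f) parallel::mclapply(x, f, mc.cores = threads)
  } else {
    function(x, f) lapply(x, f)
  }

  reads <- apply_fun(seq_len(nrow(disc$files)), function(i) {
    tryCatch(list(cg = readABIF(disc$files$path[i])),
             error = function(e) list(error = conditionMessage(e)))
  })
  failed <- vapply(reads, function(r) !is.null(r$error), logical(1))
  read_rejects <- data.frame(
    path = disc$files$path[failed],
    reason = vapply(reads[failed], function(r) r$error, character(1)),
    stringsAsFactors = FALSE)
  rejects <- rbind(disc$rejects, read_rejects)
  chroms <- lapply(reads[!failed], function(r) r$cg)
  say("read ", length(chroms), " trace(s); ", sum(failed), " unreadable")
  if (length(chroms) == 0L) stop("no readable .ab1 files under ", inputDir)

  metrics_list <- apply_fun(chroms, function(cg)
    summariseQuality(cg, config))
  metrics <- do.call(rbind, metrics_list)

  dd <- dedupeReplicates(metrics)
  metrics <- dd$kept
  names(chroms) <- vapply(metrics_list, function(m) m$source_path,
                          character(1))
  chroms <- chroms[metrics$source_path]
  names(chroms) <- metrics$sequence_id

  verdicts <- applyFilters(metrics, config)
  metrics_v <- cbind(metrics,
                     verdicts[, c("passed", "failed_criteria")])

  events <- NULL
  if (!isTRUE(is.na(fcsDir))) {
    fdir <- if (is.null(fcsDir)) inputDir else fcsDir
    fcs_files <- list.files(fdir, pattern = "\\.fcs$", recursive = TRUE,
                            full.names = TRUE, ignore.case = TRUE)
    stems <- tools::file_path_sans_ext(basename(fcs_files))
    hit <- stems %in% unique(metrics$plate_id)
    if (!is.null(fcsDir) && length(fcs_files) && !any(hit)) {
      warning("no FCS files match plate folder names; ",
              "running in sequence-only mode")
    }
    if (any(hit)) {
      ev_list <- lapply(fcs_files[hit], readFCSIndex)
      events <- do.call(rbind, ev_list)
      if (!is.null(gates)) {
        labels <- gateEvents(events, gates)
        events <- cbind(events, as.data.frame(labels, optional = TRUE))
      }
      say("loaded ", nrow(events), " index-sort event(s) from ",
          sum(hit), " FCS file(s)")
    }
  }

  mw <- matchWells(metrics_v, events)
  records <- mw$records

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- c(fasta = file.path(outDir, "sequences.fasta"),
               summary = file.path(outDir, "summary.tsv"),
               report_html = file.path(outDir, "report.html"),
               report_md = file.path(outDir, "report.md"),
               rejects = file.path(outDir, "rejects.tsv"))
  writeFasta(records, chroms, outputs[["fasta"]])
  writeSummaryTable(records, outputs[["summary"]])
  qualityReport(records, config, outputs[["report_html"]])
  utils::write.table(rejects, outputs[["rejects"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # manual-inspection electropherograms for CDR3-failing sequences only
  eg_dir <- file.path(outDir, "electropherograms")
  cdr3_fail <- metrics_v$sequence_id[
    grepl("max_cdr3_secondary_peaks", metrics_v$failed_criteria)]
  if (length(cdr3_fail)) {
    dir.create(eg_dir, showWarnings = FALSE)
    for (id in sort(cdr3_fail)) {
      plotCdr3Electropherogram(chroms[[id]], config@cdr3Start,
                               config@cdr3End,
                               file.path(eg_dir, paste0(id, "_cdr3.png")),
                               ratio = config@secondaryPeakRatio)
    }
    outputs <- c(outputs, electropherograms = eg_dir)
  }

  if (!is.null(events)) {
    chan <- setdiff(names(events),
                    c("plate_id", "well_id",
                      if (!is.null(gates)) gates@probes))
    chan <- chan[vapply(events[chan], is.numeric, logical(1))]
    fluo <- setdiff(chan, c("FSC-A", "SSC-A"))
    if (length(fluo) >= 2L) {
      dp_dir <- file.path(outDir, "density_plots")
      dir.create(dp_dir, showWarnings = FALSE)
      for (p in sort(unique(events$plate_id))) {
        ev <- events[events$plate_id == p, , drop = FALSE]
        fcsDensityPlot(ev, fluo[1], fluo[2], gates = gates,
                       outPath = file.path(dp_dir, paste0(p, ".png")))
      }
      outputs <- c(outputs, density_plots = dp_dir)
    }
  }

  say("wrote outputs to ", outDir)
  invisible(list(records = records, metrics = metrics_v,
                 unmatched = mw$unmatched, outputs = outputs,
                 rejects = rejects, config = config))
}
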