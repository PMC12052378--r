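fake_metrics <- function(wells, plate = "p1", passed = TRUE) {
  n <- length(wells)
  cbind(
    data.frame(sequence_id = paste0(plate, "_", wells),
               plate_id = plate, well_id = wells,
               source_path = paste0(wells, ".ab1"),
               raw_length = 700L, raw_mean_quality = 45,
               trim_start = 5L, trim_end = 690L,
               trimmed_mean_quality = 50, trimmed_length = 686L,
               cdr3_secondary_peaks = 0L, total_secondary_peaks = 0L,
               stringsAsFactors = FALSE),
    data.frame(passed = rep(passed, length.out = n),
               failed_criteria = ifelse(rep(passed, length.out = n), "",
                                        "min_trimmed_mean_quality")))
}

fake_events <- function(wells, plate = "p1") {
  data.frame(plate_id = plate, well_id = wells,
             `PreF-PE` = seq_along(wells) * 100,
             check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("fully matched plates join with nothing unmatched", {
  wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), 1:12)
  mw <- matchWells(fake_metrics(wells), fake_events(wells))
  expect_identical(nrow(mw$records), 96L)
  expect_true(all(mw$records$has_metrics & mw$records$has_event))
  expect_identical(mw$unmatched$sequence_only, 0L)
  expect_identical(mw$unmatched$index_only, 0L)
})

test_that("partial overlap produces the outer join and counts", {
  mw <- matchWells(fake_metrics(c("A01", "B01", "C01")),
                   fake_events(c("A01", "D01")))
  expect_identical(nrow(mw$records), 4L)
  expect_identical(mw$unmatched$sequence_only, 2L)
  expect_identical(mw$unmatched$index_only, 1L)
  d01 <- mw$records[mw$records$well_id == "D01", ]
  expect_false(d01$has_metrics)
  expect_true(d01$has_event)
})

test_that("sequence-only analyses complete without cytometry input", {
  mw <- matchWells(fake_metrics(c("A01", "B01")), NULL)
  expect_identical(nrow(mw$records), 2L)
  expect_true(all(!mw$records$has_event))
})

test_that("duplicate wells on the cytometry side are an error", {
  expect_error(matchWells(fake_metrics("A01"),
                          fake_events(c("A01", "A01"))),
               "duplicate")
})

test_that("FASTA output is untrimmed, pass-only, and header-stable", {
  dir <- withr::local_tempdir()
  wells <- c("A01", "A02", "A03")
  m <- fake_metrics(wells)
  m$passed <- c(TRUE, FALSE, TRUE)
  m$failed_criteria <- c("", "min_trim_end", "")
  mw <- matchWells(m, NULL)
  chroms <- lapply(wells, function(w)
    makeChromatogram(120, "good", plateId = "p1", wellId = w))
  names(chroms) <- paste0("p1_", wells)
  fa_path <- file.path(dir, "out.fasta")
  writeFasta(mw$records, chroms, fa_path)
  fa <- Biostrings::readDNAStringSet(fa_path)
  expect_identical(names(fa), c("p1_A01", "p1_A03"))
  expect_identical(as.character(fa[["p1_A01"]]),
                   baseCalls(chroms[["p1_A01"]]))
  # untrimmed: record length equals the full called length
  expect_true(all(Biostrings::width(fa) == 120L))
  # zero passing -> valid empty FASTA
  m$passed <- FALSE
  writeFasta(matchWells(m, NULL)$records, chroms, fa_path)
  expect_length(Biostrings::readDNAStringSet(fa_path), 0L)
  # passing record without chromatogram -> error
  m$passed <- TRUE
  expect_error(writeFasta(matchWells(m, NULL)$records, list(), fa_path),
               "no chromatogram")
})

test_that("summary table re-reads to the same pass/fail accounting", {
  dir <- withr::local_tempdir()
  m <- fake_metrics(c("A01", "B01", "C01"))
  m$passed <- c(TRUE, TRUE, FALSE)
  m$failed_criteria <- c("", "", "max_trim_start;min_trim_end")
  mw <- matchWells(m, fake_events(c("A01", "E01")))
  path <- file.path(dir, "summary.tsv")
  out <- writeSummaryTable(mw$records, path)
  expect_identical(nrow(out), nrow(mw$records))
  back <- utils::read.delim(path, na.strings = "")
  expect_identical(nrow(back), nrow(mw$records))
  expect_identical(sum(back$passed %in% TRUE), 2L)
  expect_identical(sum(back$passed %in% FALSE), 1L)
  expect_identical(back$failed_criteria[back$well_id == "C01"],
                   "max_trim_start;min_trim_end")
})

test_that("electropherogram highlights exactly the secondary positions", {
  dir <- withr::local_tempdir()
  inj <- c(105, 120, 130)
  cg <- makeChromatogram(300, "good", injections = inj,
                         injectionRatio = 0.5, seed = 41,
                         plateId = "p1", wellId = "A01")
  path <- file.path(dir, "cdr3.png")
  info <- plotCdr3Electropherogram(cg, 100, 150, path, ratio = 0.33)
  expect_true(file.exists(path) && file.info(path)$size > 0)
  expect_identical(info$highlighted, as.integer(inj))
  expect_length(info$highlighted,
                countSecondaryPeaks(cg, 100, 150, ratio = 0.33))
  expect_error(plotCdr3Electropherogram(cg, 400, 500, path), "outside")
})

test_that("report totals agree with the record table, per plate", {
  dir <- withr::local_tempdir()
  m <- rbind(fake_metrics(c("A01", "B01"), plate = "p1"),
             fake_metrics(c("A01", "C01"), plate = "p2"))
  m$passed <- c(TRUE, FALSE, TRUE, TRUE)
  m$failed_criteria <- ifelse(m$passed, "", "min_trim_end")
  mw <- matchWells(m, fake_events(c("A01", "B01"), plate = "p1"))
  cfg <- filterPreset("bcr_default")
  rep_out <- qualityReport(mw$records, cfg, file.path(dir, "report.html"))
  expect_true(file.exists(rep_out$html))
  expect_true(file.exists(rep_out$markdown))
  sec <- rep_out$sections
  expect_identical(length(sec$per_plate), 2L)
  expect_identical(sec$overall$n_pass, 3L)
  expect_equal(sec$overall$pass_rate, 3 / 4)
  pr <- vapply(sec$per_plate, function(p) p$pass_rate, numeric(1))
  expect_equal(pr, c(1 / 2, 1))
  # the exact thresholds used are listed
  md <- readLines(rep_out$markdown)
  expect_true(any(grepl("min_raw_length", md)))
  expect_true(any(grepl(sprintf("\\b%g\\b", cfg@minRawLength), md)))
  # byte-identical on rerun (no timestamps embedded)
  md1 <- readBin(rep_out$markdown, "raw", file.info(rep_out$markdown)$size)
  qualityReport(mw$records, cfg, file.path(dir, "report.html"))
  md2 <- readBin(rep_out$markdown, "raw", file.info(rep_out$markdown)$size)
  expect_identical(md1, md2)
})
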