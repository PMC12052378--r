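make_events <- function(wells, channels = c("FITC-A", "APC-A"), seed = 1) {
  set.seed(seed)
  ev <- data.frame(well_id = wells, stringsAsFactors = FALSE)
  for (ch in channels) ev[[ch]] <- round(stats::runif(length(wells), 0, 1e4), 2)
  ev
}

test_that("FCS write/read round-trips events to float32 precision", {
  dir <- withr::local_tempdir()
  ev <- make_events(c("A01", "B02", "C03"))
  path <- file.path(dir, "plate1.fcs")
  writeFCS(ev, c("FITC-A", "APC-A"), path)
  got <- readFCSIndex(path)
  expect_identical(got$plate_id, rep("plate1", 3))
  expect_identical(got$well_id, ev$well_id)
  expect_equal(got$`FITC-A`, ev$`FITC-A`, tolerance = 1e-6)
  expect_equal(got$`APC-A`, ev$`APC-A`, tolerance = 1e-6)
})

test_that("a full 96-well plate decodes to the complete well set", {
  wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12), 1:12)
  path <- file.path(withr::local_tempdir(), "full.fcs")
  writeFCS(make_events(wells), c("FITC-A", "APC-A"), path)
  got <- readFCSIndex(path)
  expect_setequal(got$well_id, wells)
  expect_identical(nrow(got), 96L)
})

test_that("zero events yield a valid empty file", {
  path <- file.path(withr::local_tempdir(), "empty.fcs")
  writeFCS(make_events(character(0)), c("FITC-A", "APC-A"), path)
  got <- readFCSIndex(path)
  expect_identical(nrow(got), 0L)
})

test_that("randomized fixtures round-trip exactly", {
  dir <- withr::local_tempdir()
  all_wells <- sprintf("%s%02d", rep(LETTERS[1:16], each = 24), 1:24)
  set.seed(99)
  for (i in 1:10) {
    wells <- sample(all_wells, sample(1:60, 1))
    chans <- paste0("CH", seq_len(sample(1:5, 1)))
    ev <- make_events(wells, chans, seed = i)
    path <- file.path(dir, sprintf("r%02d.fcs", i))
    writeFCS(ev, chans, path)
    got <- readFCSIndex(path)
    expect_identical(got$well_id, ev$well_id)
    for (ch in chans) expect_equal(got[[ch]], ev[[ch]], tolerance = 1e-6)
  }
})

test_that("HEADER offsets audit against the TEXT keyword values", {
  path <- file.path(withr::local_tempdir(), "audit.fcs")
  ev <- make_events(c("A01", "B02", "C03", "D04"))
  writeFCS(ev, c("FITC-A", "APC-A"), path)
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  expect_identical(rawToChar(bytes[1:6]), "FCS3.1")
  off <- function(i) as.integer(trimws(rawToChar(
    bytes[(10 + 8 * (i - 1) + 1):(10 + 8 * i)])))
  txt <- rawToChar(bytes[(off(1) + 1):(off(2) + 1)])
  delim <- substr(txt, 1, 1)
  kv <- strsplit(substr(txt, 2, nchar(txt)), delim, fixed = TRUE)[[1]]
  kw <- stats::setNames(kv[seq(2, length(kv), 2)],
                        kv[seq(1, length(kv), 2)])
  expect_identical(as.integer(kw[["$BEGINDATA"]]), off(3))
  expect_identical(as.integer(kw[["$ENDDATA"]]), off(4))
  expect_identical(as.integer(kw[["$TOT"]]), 4L)
  expect_identical(as.integer(kw[["$PAR"]]), 2L)
  # DATA segment length matches $TOT x $PAR float32
  expect_identical(off(4) - off(3) + 1L, 4L * 2L * 4L)
})

test_that("files without index-sort keywords raise a distinct error", {
  # hand-build a minimal FCS 3.1 file with no index keywords
  path <- file.path(withr::local_tempdir(), "noindex.fcs")
  kw <- c("$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
          "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
          "$BYTEORD" = "1,2,3,4", "$DATATYPE" = "F", "$MODE" = "L",
          "$NEXTDATA" = "0", "$PAR" = "1", "$TOT" = "1",
          "$P1N" = "FITC-A", "$P1B" = "32", "$P1E" = "0,0",
          "$P1R" = "262144")
  body <- paste0("/", paste0(names(kw), "/", kw, "/", collapse = ""))
  data_begin <- 64L + nchar(body)
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d", 64L,
                    64L + nchar(body) - 1L, data_begin, data_begin + 3L,
                    0L, 0L)
  con <- file(path, "wb")
  writeBin(charToRaw(paste0(header, strrep(" ", 64 - 58), body)), con)
  writeBin(1.5, con, size = 4, endian = "little")
  close(con)
  expect_error(readFCSIndex(path), "no index data")
})

test_that("unsupported versions and truncated files are rejected", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "v2.fcs")
  writeBin(charToRaw(sprintf("FCS2.0    %s", strrep(" ", 48))), bad)
  expect_error(readFCSIndex(bad), "version")
  short <- file.path(dir, "short.fcs")
  writeBin(charToRaw("FCS3.1"), short)
  expect_error(readFCSIndex(short), "truncated")
})

test_that("gating uses a closed threshold and labels multi-probe events", {
  ev <- data.frame(well_id = c("A01", "A02", "A03"),
                   FITC = c(99.9, 100, 500), APC = c(600, 10, 700))
  gates <- gateConfig(c("PreF", "PostF"), c("FITC", "APC"), c(100, 500))
  lab <- gateEvents(ev, gates)
  expect_identical(lab[, "PreF"], c(FALSE, TRUE, TRUE))
  expect_identical(lab[, "PostF"], c(TRUE, FALSE, TRUE))
  # event positive for both probes is labelled for both
  expect_true(all(lab[3, ]))
  expect_error(gateEvents(ev, gateConfig("X", "PE", 1)), "PE")
})

test_that("gating is monotone in the threshold", {
  set.seed(42)
  ev <- data.frame(well_id = sprintf("A%02d", 1:12),
                   FITC = rnorm(12, 100, 50))
  counts <- vapply(seq(0, 300, by = 10), function(thr) {
    sum(gateEvents(ev, gateConfig("P", "FITC", thr))[, 1])
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("bimodal channel gates recover the generating mode counts", {
  set.seed(7)
  n_hi <- 40L
  n_lo <- 56L
  vals <- c(rnorm(n_lo, 200, 50), rnorm(n_hi, 5000, 800))
  ev <- data.frame(
    well_id = sprintf("%s%02d", rep(LETTERS[1:8], each = 12), 1:12),
    Probe = vals)
  lab <- gateEvents(ev, gateConfig("P", "Probe", 2500))
  expect_identical(sum(lab[, 1]), sum(vals >= 2500))
  expect_identical(sum(lab[, 1]), n_hi) # modes are ~6 SD apart
})

test_that("density plot writes a file and reports its gate lines", {
  ev <- make_events(sprintf("A%02d", 1:12))
  ev$plate_id <- "plateZ"
  gates <- gateConfig(c("PreF", "PostF"), c("FITC-A", "APC-A"), c(5e3, 6e3))
  path <- file.path(withr::local_tempdir(), "dens.png")
  info <- fcsDensityPlot(ev, "FITC-A", "APC-A", gates, path)
  expect_true(file.exists(path) && file.info(path)$size > 0)
  expect_identical(info$xlab, "FITC-A")
  expect_identical(info$ylab, "APC-A")
  expect_identical(info$gate_x, 5e3)
  expect_identical(info$gate_y, 6e3)
  expect_error(fcsDensityPlot(ev[0, ], "FITC-A", "APC-A", NULL,
                              path), "no events")
})
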