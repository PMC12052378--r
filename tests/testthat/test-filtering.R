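metrics_row <- function(raw_length = 700, trim_start = 5, trim_end = 690,
                        trimmed_mean_quality = 50,
                        cdr3_secondary_peaks = 0, id = "p_A01") {
  data.frame(sequence_id = id, plate_id = "p", well_id = "A01",
             source_path = paste0(id, ".ab1"), raw_length = raw_length,
             raw_mean_quality = 45, trim_start = trim_start,
             trim_end = trim_end,
             trimmed_mean_quality = trimmed_mean_quality,
             trimmed_length = max(trim_end - trim_start + 1, 0),
             cdr3_secondary_peaks = cdr3_secondary_peaks,
             total_secondary_peaks = cdr3_secondary_peaks,
             stringsAsFactors = FALSE)
}

test_that("mouse TCR preset carries the adjusted length and trim end", {
  cfg <- filterPreset("tcr_mouse")
  expect_identical(cfg@minRawLength, 200)
  expect_identical(cfg@minTrimEnd, 250)
  v <- applyFilters(metrics_row(raw_length = 199, trim_end = 260), cfg)
  expect_false(v$passed)
  expect_match(v$failed_criteria, "min_raw_length")
  v2 <- applyFilters(metrics_row(raw_length = 200, trim_end = 260), cfg)
  expect_false(grepl("min_raw_length", v2$failed_criteria))
  expect_true(v2$passed)
})

test_that("metrics exactly at every threshold pass (closed bounds)", {
  cfg <- filterPreset("bcr_default")
  m <- metrics_row(raw_length = cfg@minRawLength,
                   trim_start = cfg@maxTrimStart,
                   trim_end = cfg@minTrimEnd,
                   trimmed_mean_quality = cfg@minTrimmedMeanQuality,
                   cdr3_secondary_peaks = cfg@maxCdr3SecondaryPeaks)
  v <- applyFilters(m, cfg)
  expect_true(v$passed)
  expect_identical(v$failed_criteria, "")
})

test_that("undefined trim fails both trim criteria", {
  v <- applyFilters(metrics_row(trim_start = 0, trim_end = 0,
                                trimmed_mean_quality = 0),
                    filterPreset("bcr_default"))
  expect_match(v$failed_criteria, "max_trim_start")
  expect_match(v$failed_criteria, "min_trim_end")
})

test_that("verdicts match a direct conjunction-of-comparisons oracle", {
  cfg <- filterPreset("bcr_default")
  set.seed(20)
  for (i in 1:400) {
    m <- metrics_row(raw_length = sample(0:800, 1),
                     trim_start = sample(0:120, 1),
                     trim_end = sample(0:800, 1),
                     trimmed_mean_quality = runif(1, 0, 62),
                     cdr3_secondary_peaks = sample(0:20, 1))
    if (m$trim_start == 0) m$trim_end <- 0
    if (m$trim_end < m$trim_start) m$trim_end <- m$trim_start
    v <- applyFilters(m, cfg)
    want <- m$raw_length >= cfg@minRawLength &
      m$trim_start >= 1 & m$trim_start <= cfg@maxTrimStart &
      m$trim_start >= 1 & m$trim_end >= cfg@minTrimEnd &
      m$trimmed_mean_quality >= cfg@minTrimmedMeanQuality &
      m$cdr3_secondary_peaks <= cfg@maxCdr3SecondaryPeaks
    expect_identical(v$passed, want)
    expect_identical(v$passed, !nzchar(v$failed_criteria))
  }
})

test_that("tightening a threshold never converts fail into pass", {
  set.seed(21)
  base <- filterPreset("bcr_default")
  for (i in 1:50) {
    m <- metrics_row(raw_length = sample(300:500, 1),
                     trim_start = sample(1:80, 1),
                     trim_end = sample(300:500, 1),
                     trimmed_mean_quality = runif(1, 20, 40),
                     cdr3_secondary_peaks = sample(0:10, 1))
    before <- applyFilters(m, base)$passed
    tight <- filterPreset("bcr_default",
                          min_raw_length = base@minRawLength + 50,
                          max_trim_start = base@maxTrimStart - 10,
                          min_trimmed_mean_quality =
                            base@minTrimmedMeanQuality + 5)
    after <- applyFilters(m, tight)$passed
    expect_false(!before && after)
  }
})

test_that("replicate dedup keeps the best quality, audits the rest", {
  m <- rbind(
    within(metrics_row(trimmed_mean_quality = 40), source_path <- "b.ab1"),
    within(metrics_row(trimmed_mean_quality = 55), source_path <- "a.ab1"),
    within(metrics_row(id = "p_B01"), well_id <- "B01"))
  dd <- dedupeReplicates(m)
  expect_identical(nrow(dd$kept), 2L)
  kept_a01 <- dd$kept[dd$kept$well_id == "A01", ]
  expect_identical(kept_a01$trimmed_mean_quality, 55)
  expect_identical(dd$removed$source_path, "b.ab1")
  expect_identical(dd$removed$removed_reason, "technical replicate")
})

test_that("dedup is identity on unique wells and deterministic on ties", {
  m <- metrics_row()
  expect_identical(dedupeReplicates(m)$kept, m)
  ties <- rbind(
    within(metrics_row(), source_path <- "z.ab1"),
    within(metrics_row(), source_path <- "a.ab1"),
    within(metrics_row(), source_path <- "m.ab1"))
  dd <- dedupeReplicates(ties)
  expect_identical(dd$kept$source_path, "a.ab1")
  expect_error(dedupeReplicates(m, policy = "random"), "policy")
})

test_that("pass and fail sets partition the deduped input", {
  set.seed(22)
  rows <- lapply(1:30, function(i) {
    r <- metrics_row(raw_length = sample(200:800, 1),
                     trimmed_mean_quality = runif(1, 0, 62),
                     id = sprintf("p_W%02d", i))
    r$well_id <- sprintf("W%02d", i)
    r
  })
  m <- do.call(rbind, rows)
  v <- applyFilters(m, filterPreset("bcr_default"))
  expect_identical(sum(v$passed) + sum(!v$passed), nrow(m))
  expect_length(intersect(which(v$passed), which(!v$passed)), 0L)
})

test_that("config files round-trip through the preset dialect", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "filters.cfg")
  cfg <- filterPreset("bcr_default", min_raw_length = 333,
                      secondary_peak_ratio = 0.25)
  writeFilterConfig(cfg, path, name = "custom")
  got <- readFilterConfig(path, "custom")
  for (s in slotNames(cfg)) {
    expect_identical(slot(got, s), slot(cfg, s), label = s)
  }
  expect_error(readFilterConfig(path, "nope"), "not found")
  writeLines(c("[x]", "bogus_key = 1"), file.path(dir, "bad.cfg"))
  expect_error(readFilterConfig(file.path(dir, "bad.cfg")), "unknown")
})
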