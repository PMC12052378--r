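# Ground-truthed synthetic chromatograms and index-sort fixtures. Written
# files use exactly the ABIF/FCS dialects the readers consume, so the
# whole pipeline is testable without any downloaded data. Phred values are
# assigned from the regime (QC consumes the stored qualities, so ground
# truth must live there); peak spacing is fixed per trace and no
# mobility-shift or dye-blob artifacts are simulated.

.GOOD_QUALITY_MEAN <- 50
.GOOD_QUALITY_SD <- 2
.BAD_QUALITY_MEAN <- 5
.BAD_QUALITY_SD <- 2

#' Synthesize one Sanger chromatogram
#'
#' Builds a [Chromatogram-class] with one Gaussian peak per called base.
#' In the \code{"good"} regime each base has a single dominant channel
#' with ~2 % baseline noise on the other three and Phred qualities around
#' 50 that decay toward the read ends, as in clean capillary traces. The
#' \code{"bad"} regime emulates an empty-well well: comparable low
#' amplitudes on all four channels and qualities around 5. Secondary
#' peaks — a second channel at a set fraction of the dominant one, the
#' signature of a mixed template — can be injected at chosen base
#' positions.
#'
#' Peak locations are 0-based trace-sample indices at
#' \code{spacing * (b - 1) + spacing/2} for base \code{b}, so a 10-base
#' trace at spacing 12 peaks at 6, 18, ..., 114.
#'
#' @param length number of called bases (>= 1).
#' @param quality regime, \code{"good"} or \code{"bad"}.
#' @param injections integer vector of base positions (1-based) receiving
#'   an injected secondary peak; must lie within the read.
#' @param injectionRatio secondary/primary amplitude of injections.
#' @param seed optional seed; when given the trace is a pure function of
#'   the arguments.
#' @param peakSpacing trace samples per base (default 12).
#' @param peakSigma Gaussian peak width in trace samples.
#' @param qualityMean,qualitySd override the regime's Phred distribution.
#' @param endDecay number of bases over which quality decays at each read
#'   end (good regime only).
#' @param plateId,wellId metadata stamped on the object.
#' @return a valid [Chromatogram-class].
#' @examples
#' cg <- makeChromatogram(60, quality = "good", injections = c(20, 30),
#'                        injectionRatio = 0.5, seed = 42)
#' countSecondaryPeaks(cg, ratio = 0.33)
#' @export
makeChromatogram <- function(length, quality = c("good", "bad"),
                             injections = integer(0), injectionRatio = 0.5,
                             seed = NULL, peakSpacing = 12L, peakSigma = 3,
                             qualityMean = NULL, qualitySd = NULL,
                             endDecay = 20L, plateId = "", wellId = "") {
  quality <- match.arg(quality)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("length must be a positive integer")
  injections <- as.integer(injections)
  if (any(injections < 1L | injections > length)) {
    stop("injection position outside the read")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(qualityMean)) {
    qualityMean <- if (quality == "good") .GOOD_QUALITY_MEAN else .BAD_QUALITY_MEAN
  }
  if (is.null(qualitySd)) {
    qualitySd <- if (quality == "good") .GOOD_QUALITY_SD else .BAD_QUALITY_SD
  }

  channels <- c("G", "A", "T", "C")
  ntrace <- length * peakSpacing
  traces <- matrix(0, nrow = ntrace, ncol = 4L,
                   dimnames = list(NULL, channels))
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  centers <- peakSpacing * (seq_len(length) - 1L) + peakSpacing %/% 2L
  half <- max(3L, ceiling(4 * peakSigma))

  add_peak <- function(ch, center, amp) {
    lo <- max(0L, center - half)
    hi <- min(ntrace - 1L, center + half)
    idx <- lo:hi
    traces[idx + 1L, ch] <<- traces[idx + 1L, ch] +
      amp * exp(-((idx - center)^2) / (2 * peakSigma^2))
  }

  for (b in seq_len(length)) {
    ch <- match(bases[b], channels)
    if (quality == "good") {
      amp <- stats::rnorm(1, 1500, 120)
      amp <- min(max(amp, 400), 30000)
      add_peak(ch, centers[b], amp)
      # baseline chatter on the other channels, well below any
      # secondary-peak calling ratio
      for (o in setdiff(1:4, ch)) {
        add_peak(o, centers[b], stats::runif(1, 0, 0.02 * amp))
      }
    } else {
      # empty-well garbage: all channels at comparable low amplitude
      for (o in 1:4) add_peak(o, centers[b], stats::runif(1, 20, 120))
      amp <- max(traces[centers[b] + 1L, ])
    }
    if (b %in% injections) {
      alt <- setdiff(1:4, ch)[1]
      add_peak(alt, centers[b], injectionRatio * amp)
    }
  }

  q <- stats::rnorm(length, qualityMean, qualitySd)
  if (quality == "good" && endDecay > 0L && length > 2L * endDecay) {
    ramp <- 35 * (1 - (seq_len(endDecay) - 1L) / endDecay)
    q[seq_len(endDecay)] <- q[seq_len(endDecay)] - ramp
    q[length - seq_len(endDecay) + 1L] <- q[length - seq_len(endDecay) + 1L] - ramp
  }
  q <- as.integer(round(pmin(pmax(q, 0), 62)))

  tr <- round(traces)
  storage.mode(tr) <- "integer"
  new("Chromatogram",
      sourcePath = "", plateId = plateId, wellId = wellId,
      channelOrder = "GATC", traces = tr,
      peakLocations = as.integer(centers),
      baseCalls = paste(bases, collapse = ""),
      qualities = q)
}

#' Specification of a synthetic plate
#'
#' Collects the generator settings for one plate of index-sorted,
#' Sanger-sequenced wells: how many wells are in the good (clean trace)
#' and bad (empty-well garbage) regimes, amplicon geometry, the Phred
#' distributions of the two regimes, optional secondary-peak injections,
#' and the fluorescence modes of the antigen probes. The defaults emulate
#' full-length heavy-chain BCR amplicons (700 bases) from a plate that
#' includes a fraction of empty wells, with two probe channels whose
#' negative and positive modes are well separated.
#'
#' @param nGood,nBad wells per regime (together at most 96).
#' @param plateId plate folder name.
#' @param ampliconLength called bases per trace.
#' @param peakSpacing,peakSigma trace geometry (samples per base, peak
#'   width).
#' @param goodQualityMean,goodQualitySd,badQualityMean,badQualitySd Phred
#'   distributions of the regimes.
#' @param endDecayLength bases of end-of-read quality decay.
#' @param secondaryInjections named list: well label -> list(positions =
#'   integer vector, ratio = numeric).
#' @param probeChannels data.frame with columns \code{name},
#'   \code{neg_mean}, \code{neg_sd}, \code{pos_mean}, \code{pos_sd}.
#' @param seed integer seed; the whole plate is a pure function of the
#'   spec.
#' @return a list of class \code{"SyntheticPlateSpec"}.
#' @export
syntheticPlateSpec <- function(nGood = 8L, nBad = 4L, plateId = "plate01",
    ampliconLength = 700L, peakSpacing = 12L, peakSigma = 3,
    goodQualityMean = .GOOD_QUALITY_MEAN, goodQualitySd = .GOOD_QUALITY_SD,
    badQualityMean = .BAD_QUALITY_MEAN, badQualitySd = .BAD_QUALITY_SD,
    endDecayLength = 20L, secondaryInjections = list(),
    probeChannels = data.frame(
      name = c("PreF-PE", "PostF-APC"),
      neg_mean = c(200, 250), neg_sd = c(50, 60),
      pos_mean = c(5000, 6000), pos_sd = c(800, 900)),
    seed = 1L) {
  spec <- list(nGood = as.integer(nGood), nBad = as.integer(nBad),
               plateId = plateId, ampliconLength = as.integer(ampliconLength),
               peakSpacing = as.integer(peakSpacing), peakSigma = peakSigma,
               goodQualityMean = goodQualityMean, goodQualitySd = goodQualitySd,
               badQualityMean = badQualityMean, badQualitySd = badQualitySd,
               endDecayLength = as.integer(endDecayLength),
               secondaryInjections = secondaryInjections,
               probeChannels = probeChannels, seed = as.integer(seed))
  if (spec$nGood < 0L || spec$nBad < 0L || spec$nGood + spec$nBad < 1L) {
    stop("need at least one well")
  }
  if (spec$nGood + spec$nBad > 96L) stop("at most 96 wells per plate")
  if (any(probeChannels$pos_mean <= probeChannels$neg_mean)) {
    stop("probe positive mode must exceed the negative mode")
  }
  if (any(c(probeChannels$neg_sd, probeChannels$pos_sd,
            goodQualitySd, badQualitySd) <= 0)) {
    stop("all mode standard deviations must be positive")
  }
  class(spec) <- "SyntheticPlateSpec"
  spec
}

#' Generate a synthetic plate on disk
#'
#' Writes one plate folder of ABIF traces (file names
#' \code{<well>_synth.ab1}), a matching index-sort FCS file named after
#' the plate, and a tab-separated ground-truth manifest recording each
#' well's regime, injected secondary-peak positions and per-probe mode.
#' Wells are filled row-major from A01; the first \code{nGood} wells carry
#' good-regime traces, the rest bad-regime traces. Each well's probe modes
#' are drawn at random (recorded in the manifest), and its fluorescence is
#' sampled from the corresponding mode of the probe channel. Everything is
#' deterministic in \code{spec$seed}.
#'
#' @param spec a [syntheticPlateSpec()].
#' @param outDir directory under which the plate folder is created.
#' @return invisibly, a list: \code{dir} (plate folder), \code{fcs},
#'   \code{manifest_path}, \code{manifest} (data.frame), \code{files}
#'   (trace paths).
#' @examples
#' \donttest{
#' plate <- makePlate(syntheticPlateSpec(nGood = 3, nBad = 2, seed = 7),
#'                    tempfile("plate"))
#' plate$manifest
#' }
#' @export
makePlate <- function(spec, outDir) {
  stopifnot(inherits(spec, "SyntheticPlateSpec"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  plate_dir <- file.path(outDir, spec$plateId)
  dir.create(plate_dir, showWarnings = FALSE)

  n <- spec$nGood + spec$nBad
  wells <- sprintf("%s%02d", rep(LETTERS[1:8], each = 12L),
                   rep(1:12, times = 8L))[seq_len(n)]
  regimes <- c(rep("good", spec$nGood), rep("bad", spec$nBad))

  set.seed(spec$seed)
  probes <- spec$probeChannels
  files <- character(n)
  manifest <- vector("list", n)
  fluo <- matrix(NA_real_, nrow = n, ncol = nrow(probes) + 2L,
                 dimnames = list(NULL, c("FSC-A", "SSC-A", probes$name)))

  for (i in seq_len(n)) {
    w <- wells[i]
    inj <- spec$secondaryInjections[[w]]
    pos <- if (is.null(inj)) integer(0) else as.integer(inj$positions)
    ratio <- if (is.null(inj)) 0.5 else inj$ratio
    qm <- if (regimes[i] == "good") spec$goodQualityMean else spec$badQualityMean
    qs <- if (regimes[i] == "good") spec$goodQualitySd else spec$badQualitySd
    cg <- makeChromatogram(spec$ampliconLength, quality = regimes[i],
                           injections = pos, injectionRatio = ratio,
                           peakSpacing = spec$peakSpacing,
                           peakSigma = spec$peakSigma,
                           qualityMean = qm, qualitySd = qs,
                           endDecay = spec$endDecayLength,
                           plateId = spec$plateId, wellId = w)
    files[i] <- file.path(plate_dir, paste0(w, "_synth.ab1"))
    writeABIF(cg, files[i])

    fluo[i, "FSC-A"] <- stats::rnorm(1, 50000, 5000)
    fluo[i, "SSC-A"] <- stats::rnorm(1, 30000, 4000)
    modes <- character(nrow(probes))
    for (p in seq_len(nrow(probes))) {
      positive <- stats::runif(1) < 0.5
      modes[p] <- if (positive) "pos" else "neg"
      fluo[i, probes$name[p]] <- stats::rnorm(1,
        if (positive) probes$pos_mean[p] else probes$neg_mean[p],
        if (positive) probes$pos_sd[p] else probes$neg_sd[p])
    }
    manifest[[i]] <- data.frame(
      well_id = w, regime = regimes[i],
      n_injected = length(pos),
      injected_positions = paste(pos, collapse = ","),
      stringsAsFactors = FALSE)
    for (p in seq_len(nrow(probes))) {
      manifest[[i]][[paste0(probes$name[p], "_mode")]] <- modes[p]
    }
  }
  manifest <- do.call(rbind, manifest)

  events <- cbind(data.frame(well_id = wells, stringsAsFactors = FALSE),
                  as.data.frame(fluo, optional = TRUE))
  fcs_path <- file.path(plate_dir, paste0(spec$plateId, ".fcs"))
  writeFCS(events, colnames(fluo), fcs_path)

  manifest_path <- file.path(plate_dir, "manifest.tsv")
  utils::write.table(manifest, manifest_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(dir = plate_dir, fcs = fcs_path,
                 manifest_path = manifest_path, manifest = manifest,
                 files = files))
}

#' Simulate a two-regime quality-metrics table
#'
#' Draws per-sequence quality metrics directly (without building traces)
#' from a high-quality and a low-quality regime, for exercising and
#' validating the data-driven threshold derivation. Defaults put the two
#' regimes more than six pooled standard deviations apart on every
#' varying parameter, the situation the derivation is designed for: a
#' plate set containing both clean sequences and empty-well garbage.
#' Within-regime values are draws around the regime means; \code{sd = 0}
#' yields exact duplicates of the regime means.
#'
#' @param nHigh,nLow sequences per regime.
#' @param highMeans,highSds,lowMeans,lowSds named numeric vectors over
#'   \code{raw_length}, \code{raw_mean_quality}, \code{trim_start},
#'   \code{trim_end}, \code{trimmed_mean_quality},
#'   \code{cdr3_secondary_peaks}.
#' @param seed integer seed.
#' @return data.frame of metrics with a ground-truth \code{regime}
#'   column ("high"/"low").
#' @seealso [deriveThresholds()]
#' @export
simulateQualityMetrics <- function(nHigh, nLow,
    highMeans = c(raw_length = 700, raw_mean_quality = 48, trim_start = 5,
                  trim_end = 690, trimmed_mean_quality = 50,
                  cdr3_secondary_peaks = 0.5),
    highSds = c(raw_length = 10, raw_mean_quality = 2, trim_start = 1.5,
                trim_end = 8, trimmed_mean_quality = 2,
                cdr3_secondary_peaks = 0.6),
    lowMeans = c(raw_length = 350, raw_mean_quality = 15, trim_start = 150,
                 trim_end = 250, trimmed_mean_quality = 15,
                 cdr3_secondary_peaks = 30),
    lowSds = c(raw_length = 40, raw_mean_quality = 4, trim_start = 40,
               trim_end = 50, trimmed_mean_quality = 4,
               cdr3_secondary_peaks = 5),
    seed = 1L) {
  params <- names(highMeans)
  set.seed(as.integer(seed))
  draw <- function(n, means, sds) {
    cols <- lapply(params, function(p) {
      if (sds[[p]] == 0) rep(means[[p]], n)
      else stats::rnorm(n, means[[p]], sds[[p]])
    })
    names(cols) <- params
    as.data.frame(cols)
  }
  tab <- rbind(cbind(draw(nHigh, highMeans, highSds),
                     regime = rep("high", nHigh)),
               cbind(draw(nLow, lowMeans, lowSds),
                     regime = rep("low", nLow)))
  tab$raw_length <- pmax(round(tab$raw_length), 1)
  tab$trim_start <- pmax(round(tab$trim_start), 1)
  tab$trim_end <- pmax(round(tab$trim_end), tab$trim_start)
  tab$cdr3_secondary_peaks <- pmax(round(tab$cdr3_secondary_peaks), 0)
  tab$raw_mean_quality <- pmin(pmax(tab$raw_mean_quality, 0), 62)
  tab$trimmed_mean_quality <- pmin(pmax(tab$trimmed_mean_quality, 0), 62)
  n <- nrow(tab)
  data.frame(sequence_id = sprintf("sim_%04d", seq_len(n)),
             tab[, c(params, "regime")], check.names = FALSE,
             stringsAsFactors = FALSE)
}
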