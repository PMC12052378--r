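# Data-driven derivation of filter thresholds: two-cluster k-means on
# z-scored quality parameters, PCA-based selection of parameters carrying
# > 5 % of the variance, and per-parameter bounds at n SD from the
# high-quality cluster mean. The CDR3 secondary-peak threshold is never
# derived: it is reported as manual, to be set from its distribution.

.DERIVE_PARAMS <- c("raw_length", "raw_mean_quality", "trim_start",
                    "trim_end", "trimmed_mean_quality",
                    "cdr3_secondary_peaks")

# bound direction per parameter semantics: quality-like parameters get a
# lower bound, trim_start an upper bound
.PARAM_DIRECTION <- c(
  raw_length = "lower", raw_mean_quality = "lower", trim_start = "upper",
  trim_end = "lower", trimmed_mean_quality = "lower",
  cdr3_secondary_peaks = "manual"
)

#' Derive filter thresholds from a quality-metrics table
#'
#' Reproduces the data-driven threshold-setting procedure on a table of
#' per-sequence quality metrics:
#' \enumerate{
#'   \item z-score the candidate parameters (constant parameters are set
#'     aside: they carry no variance and cannot separate clusters);
#'   \item split the sequences into two clusters by k-means (k fixed at 2,
#'     multiple restarts under the given seed); the cluster with the
#'     higher mean trimmed mean quality is the high-quality cluster;
#'   \item attribute the total variance to parameters through principal
#'     components (squared loadings weighted by each component's variance
#'     share) and select the parameters explaining more than
#'     \code{varianceCutoff} of it;
#'   \item for every selected parameter except the CDR3 secondary-peak
#'     count, place the threshold \code{nSd} standard deviations from the
#'     high-quality cluster mean, on the original scale, below the mean
#'     for quality-like parameters (raw length, trim end, mean qualities)
#'     and above it for the trim start;
#'   \item report the CDR3 secondary-peak threshold as \code{"manual"}:
#'     the CDR3 is the most variable receptor region, and its cutoff is
#'     chosen by eye from the parameter's distribution.
#' }
#'
#' @param metrics data.frame of quality metrics
#'   (see [summariseQuality()]); at least two rows.
#' @param nSd how many high-cluster standard deviations away to place each
#'   bound (default 3).
#' @param varianceCutoff minimum fraction of total variance a parameter
#'   must explain to be selected (default 0.05).
#' @param seed integer seed controlling the k-means restarts.
#' @return a list of class \code{"ThresholdDerivationResult"}:
#'   \code{selected_parameters}, \code{variance_explained} (named vector),
#'   \code{cluster_labels} (factor "high"/"low" per row),
#'   \code{high_cluster_stats} (mean and SD per parameter),
#'   \code{thresholds} (data.frame: parameter, bound, direction).
#' @seealso [thresholdsToConfig()] to turn the result into a
#'   [FilterConfig-class].
#' @export
deriveThresholds <- function(metrics, nSd = 3, varianceCutoff = 0.05,
                             seed = 1L) {
  if (nrow(metrics) < 2L) stop("need at least two sequences")
  params <- intersect(.DERIVE_PARAMS, names(metrics))
  x <- as.matrix(metrics[, params, drop = FALSE])
  storage.mode(x) <- "double"
  sds <- apply(x, 2L, stats::sd)
  live <- sds > 0
  if (!any(live)) stop("all candidate parameters are constant")
  z <- scale(x[, live, drop = FALSE])

  set.seed(as.integer(seed))
  km <- stats::kmeans(z, centers = 2L, nstart = 25L, iter.max = 100L)
  if (any(km$size == 0L)) {
    stop("degenerate clustering (empty cluster); provide more data")
  }
  mq <- tapply(metrics$trimmed_mean_quality, km$cluster, mean)
  high_cluster <- as.integer(names(mq)[which.max(mq)])
  labels <- factor(ifelse(km$cluster == high_cluster, "high", "low"),
                   levels = c("high", "low"))

  # variance attribution: squared PCA loadings weighted by each
  # component's share of total variance; fractions sum to 1 over the
  # live (z-scored) parameters
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  comp_share <- pca$sdev^2 / sum(pca$sdev^2)
  var_explained <- as.numeric((pca$rotation^2) %*% comp_share)
  names(var_explained) <- colnames(z)
  ve_all <- stats::setNames(numeric(length(params)), params)
  ve_all[names(var_explained)] <- var_explained
  selected <- names(ve_all)[ve_all > varianceCutoff]

  hi <- metrics[labels == "high", , drop = FALSE]
  stats_tab <- data.frame(
    parameter = params,
    mean = vapply(params, function(p) mean(hi[[p]]), numeric(1)),
    sd = vapply(params, function(p) stats::sd(hi[[p]]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  thr <- do.call(rbind, lapply(selected, function(p) {
    dir <- .PARAM_DIRECTION[[p]]
    st <- stats_tab[stats_tab$parameter == p, ]
    bound <- switch(dir,
      lower = st$mean - nSd * st$sd,
      upper = st$mean + nSd * st$sd,
      manual = NA_real_)
    data.frame(parameter = p, bound = bound, direction = dir,
               stringsAsFactors = FALSE)
  }))
  if (is.null(thr)) {
    thr <- data.frame(parameter = character(0), bound = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  }

  structure(list(
    selected_parameters = selected,
    variance_explained = ve_all,
    cluster_labels = labels,
    high_cluster_stats = stats_tab,
    thresholds = thr,
    n_sd = nSd, variance_cutoff = varianceCutoff, seed = as.integer(seed)
  ), class = "ThresholdDerivationResult")
}

#' @export
print.ThresholdDerivationResult <- function(x, ...) {
  cat("ThresholdDerivationResult\n")
  cat("  sequences:", length(x$cluster_labels),
      sprintf("(high %d / low %d)\n", sum(x$cluster_labels == "high"),
              sum(x$cluster_labels == "low")))
  cat("  selected parameters (> ", x$variance_cutoff * 100,
      "% of variance): ", paste(x$selected_parameters, collapse = ", "),
      "\n", sep = "")
  if (nrow(x$thresholds)) {
    for (i in seq_len(nrow(x$thresholds))) {
      t <- x$thresholds[i, ]
      cat(sprintf("  %-24s %s bound %s\n", t$parameter, t$direction,
                  if (is.na(t$bound)) "(manual)" else sprintf("%.3f", t$bound)))
    }
  }
  invisible(x)
}

#' Convert derived thresholds into a FilterConfig
#'
#' Maps a [deriveThresholds()] result onto the threshold slots of a
#' [FilterConfig-class], starting from a base config (default
#' \code{"bcr_default"}) for everything not derived — including the CDR3
#' window, the secondary-peak ratio, the trim cutoff and the manual CDR3
#' secondary-peak threshold, which the derivation deliberately leaves to
#' the user.
#'
#' @param result a \code{ThresholdDerivationResult}.
#' @param base config supplying non-derived values.
#' @return a [FilterConfig-class].
#' @export
thresholdsToConfig <- function(result, base = filterPreset("bcr_default")) {
  cfg <- base
  slot_of <- c(raw_length = "minRawLength", trim_start = "maxTrimStart",
               trim_end = "minTrimEnd",
               trimmed_mean_quality = "minTrimmedMeanQuality")
  for (i in seq_len(nrow(result$thresholds))) {
    t <- result$thresholds[i, ]
    s <- slot_of[t$parameter]
    if (!is.na(s) && !is.na(t$bound)) slot(cfg, s) <- max(t$bound, if (s == "minRawLength") 1 else -Inf)
  }
  validObject(cfg)
  cfg
}
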