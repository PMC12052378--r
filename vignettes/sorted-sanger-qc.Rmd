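---
title: "Quality control of index-sorted Sanger-sequenced immune receptors"
author: "sortSeqQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of index-sorted Sanger-sequenced immune receptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortSeqQC)
```

## Motivation and model

Index cell sorting deposits one fluorescence-characterised cell per well;
targeted PCR and Sanger sequencing of the receptor amplicon then yields one
chromatogram per well. Because whole plates are sequenced, the raw data
mixes clean traces with empty-well garbage and mixed-template reactions.
This package scores each trace, filters on those scores, and joins the
verdicts with the per-cell index-sort fluorescence. This vignette explains
the underlying procedures, the tunable parameters, and the choices made
where the design was genuinely open.

## Per-sequence quality metrics

Each chromatogram contributes six candidate quality parameters: raw read
length, raw mean Phred quality, trim start, trim end, mean Phred quality
inside the trim, and the secondary-peak count in the approximate CDR3
window (a seventh, the whole-read secondary-peak count, is reported but
not filtered on by default).

**Trim positions.** The good-quality region is located with the
modified-Mott algorithm, the de-facto standard for Sanger quality
trimming: each base contributes a score $c - p_i$, where
$p_i = 10^{-q_i/10}$ is its error probability and $c$ the cutoff
(default 0.01, i.e. Phred 20), and the reported segment is the contiguous
stretch with maximal total score. Bases better than the cutoff push the
segment outward, worse bases push it closed. If no segment scores
positive the trim is undefined, reported as $(0, 0)$ — the signature of
an empty well, and an automatic filter failure. Ties (possible because
Phred scores are integers) are broken toward the leftmost, then shortest,
maximal segment, with a $10^{-9}$ comparison epsilon so that
floating-point noise cannot promote a later segment. The trim positions
feed only the filter: output FASTA sequences are always the full,
untrimmed base calls, since downstream aligners handle soft ends better
than silently shortened reads.

**Secondary peaks.** A called position is a secondary-peak position when
the second-highest of the four dye-channel intensities at the called peak
location reaches at least a set fraction of the highest (and the highest
is positive). The default ratio of 0.33 is the convention of established
heterozygous-call detectors for Sanger traces; it is fully configurable.
Intensities are read from the stored analysed traces exactly at the
called peak index — no local-maximum search in a half-window — which is
the simplest contract that is testable against an independent
per-position check. Whether baseline subtraction should be applied first
is an open question in general; this implementation deliberately uses the
stored values as-is.

**The CDR3 window.** The complementarity-determining region 3 is the most
variable receptor segment and the critical one for clonotype analysis,
but its exact boundaries cannot be located without alignment. The window
is therefore *approximate and user-set*, in called-base coordinates
(1-based, inclusive, clamped to the read; default 100–150 for the shipped
BCR preset). A window that misses the read entirely counts zero with a
warning rather than failing, so plates with short garbage reads still
process.

## Filtering

All comparisons are closed: a metric exactly at its threshold passes (a
length filter "set at 200" admits a 200-base read). Criteria are checked
independently and every violated criterion is named in the verdict, so a
failing well is diagnosable from the summary table alone. Technical
replicates — multiple traces for one (plate, well) — are all retained at
discovery and reduced to the best trimmed mean quality just before
filtering, with ties broken by file name for determinism and the removals
audited.

Shipped presets are starting points, not claims of universality:

* `bcr_default`: min raw length 400, trim must start by base 50 and reach
  base 409, trimmed mean quality ≥ 30, at most 5 CDR3 secondary peaks,
  CDR3 window 100–150. Calibrated for full-length heavy-chain amplicons;
  the quality bound echoes the common Phred-30 comparator.
* `tcr_human`: identical values — human TCR amplicons are of comparable
  length, and published experience indicates only minor changes are
  needed; treat it as a label for "start from the BCR values and adjust".
* `tcr_mouse`: length filter 200 and trimming end position 250, the
  published adjustment for the shorter amplicons of common mouse TCR
  primer sets.

Every threshold is overridable individually (`filterPreset()` arguments)
or via the flat key-value config file dialect
(`readFilterConfig()`/`writeFilterConfig()`), which is also what the
threshold derivation emits.

## Data-driven threshold derivation

When a dataset contains both clean and failed wells in quantity, the
thresholds can be derived rather than assumed:

1. z-score the candidate parameters (constant parameters are set aside —
   they carry no variance and would make the distance metric degenerate);
2. k-means with $k = 2$ and 25 restarts under a fixed seed; the cluster
   with higher mean trimmed quality is the high-quality cluster. $k$ is
   fixed, not tunable: the procedure's semantics is a high/low split;
3. attribute total variance to parameters and select those explaining
   more than 5 %. The attribution sums squared PCA loadings weighted by
   each component's variance share; this is an interpretation of
   "fraction of variance explained by a parameter" chosen because it is
   basis-complete (fractions sum to 1) — per-cluster ANOVA would be a
   defensible alternative, and the cutoff is exposed as a parameter;
4. place each selected parameter's threshold three standard deviations
   from the high-quality cluster mean (the `nSd` parameter), on the
   original scale, below the mean for quality-like parameters (raw
   length, raw/trimmed mean quality, trim end) and above it for the trim
   start. Directions are hard-coded per parameter semantics rather than
   inferred;
5. never derive the CDR3 secondary-peak cutoff: it is reported as
   *manual*, to be set from the parameter's distribution, because the
   CDR3's variability is biological as well as technical and a 3-SD rule
   on a count with near-zero high-cluster variance would be degenerate.

On two-regime tables with ≥ 6 SD separation the derivation recovers the
generating bounds within a few percent and labels every sequence
correctly (`tests/testthat/test-acceptance.R`, `scripts/acceptance.R`).

## Index-sort integration

FCS events are decoded from the BD-style `INDEX SORTING LOCATIONS_n`
keyword family (0-based "row,col" pairs in the TEXT segment). This
dialect choice is an ecosystem convention, not a standard: the FCS
specification does not define index-sort keywords, and other sorters use
other families; the decoder is isolated so further dialects can be added.
Probe gates are closed thresholds on stored channel values — no
compensation, logicle/arcsinh transformation, or batch correction is
applied, so MFI gates should be set per batch or fluorescence normalised
upstream. Sequence metrics and events are joined by a full outer join on
(plate, well): neither side is mandatory, unmatched wells are kept and
counted, and a duplicate well on the cytometry side is an error because
index sorting deposits one cell per well.

## The synthetic generator

`makeChromatogram()` builds traces with one Gaussian peak per base
(default spacing 12 samples, width 3), a dominant channel with ≤ 2 %
baseline chatter in the good regime, and comparable low amplitudes on all
four channels in the bad regime — the empty-well signature. Phred values
are *assigned* from the regime (good: 50 ± 2 with a 20-base end decay;
bad: 5 ± 2) rather than re-estimated from the simulated signal, because
the QC consumes the stored quality tag, so the ground truth must live
there. Secondary peaks are injected at stated positions and ratios.
`makePlate()` writes a whole plate as real ABIF plus a matching FCS file
and a ground-truth manifest; `simulateQualityMetrics()` draws two-regime
metric *tables* directly for exercising the threshold derivation at
scale. The test-suite problem sizes are modest by design — 1000 random
trim vectors, 200 traces for the peak counter, 50 I/O fixtures, 20
derivation seeds at n = 1000, one 96-well end-to-end plate — chosen as
the smallest sizes at which the checked properties are not vacuous.

What the generator does *not* emulate: dye blobs, mobility shifts,
basecaller-specific peak spacing jitter, true VDJ sequence content (bases
are random; the CDR3 is positional only), and fluorescence batch effects.
Passing tests therefore demonstrate the correctness of the algorithms and
file formats, not that the shipped default thresholds are optimal for any
particular instrument or species — which is why every threshold is
user-adjustable and derivable from the user's own data.

## Numerical and degenerate-input choices

* Phred values are clamped to [0, 62] on read, with a warning — the
  byte-per-base quality convention of the trace format.
* Negative analysed-trace intensities (possible after instrument baseline
  subtraction) are clamped to zero on read.
* Wells canonicalize to uppercase letter + two-digit column ("A1" →
  "A01"), making the three-character file-name prefix rule unambiguous
  across sequencing-facility dialects; unparseable prefixes go to a
  rejects table, never silently dropped.
* An empty read is valid everywhere (zero-length tags round-trip); an
  empty events table round-trips as a valid FCS file with `$TOT` 0.
* Parallelism (`threads`) splits work per chromatogram with
  deterministic result ordering; serial and parallel runs are
  byte-identical, and reports embed no timestamps.

## Known limitations

No germline alignment or gene assignment is performed — the package ends
at filtered FASTA plus annotations, feeding standard AIRR tooling. No
fluorescence batch correction. The CDR3 window is approximate by design.
Only the ABIF and FCS 3.0/3.1 formats are read (no SCF/ZTR), and only the
BD index-sort keyword dialect is decoded.
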