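# Independent oracles used across tests. They re-derive expected values
# by direct enumeration, never by calling the code paths they check.

# O(n^2) enumeration of all contiguous segments; ties resolved toward the
# leftmost, then shortest, maximal segment
trim_oracle <- function(q, cutoff) {
  s <- cutoff - 10^(-q / 10)
  n <- length(s)
  best <- 0
  bs <- 0L
  be <- 0L
  for (i in seq_len(n)) {
    acc <- 0
    for (j in i:n) {
      acc <- acc + s[j]
      if (acc > best + 1e-9) {
        best <- acc
        bs <- i
        be <- j
      }
    }
  }
  c(bs, be)
}

# direct per-position ratio check on the stored traces
secondary_oracle <- function(cg, ws, we, ratio) {
  n <- nchar(baseCalls(cg))
  ws <- max(1L, ws)
  we <- min(n, we)
  if (ws > we) return(0L)
  count <- 0L
  tr <- traceMatrix(cg)
  locs <- peakLocations(cg)
  for (b in ws:we) {
    v <- sort(tr[locs[b] + 1L, ], decreasing = TRUE)
    if (v[1] > 0 && v[2] >= ratio * v[1]) count <- count + 1L
  }
  count
}

# a small in-memory chromatogram with hand-set channels, for tests that
# need exact control over peak intensities
manual_chromatogram <- function(intensities, qualities,
                                bases = NULL, spacing = 12L) {
  # intensities: n x 4 matrix (G, A, T, C) of peak-top values
  n <- nrow(intensities)
  if (is.null(bases)) bases <- rep("A", n)
  ntrace <- n * spacing
  traces <- matrix(0L, nrow = ntrace, ncol = 4L,
                   dimnames = list(NULL, c("G", "A", "T", "C")))
  centers <- spacing * (seq_len(n) - 1L) + spacing %/% 2L
  for (b in seq_len(n)) {
    traces[centers[b] + 1L, ] <- as.integer(intensities[b, ])
  }
  new("Chromatogram", sourcePath = "", plateId = "pl", wellId = "A01",
      channelOrder = "GATC", traces = traces,
      peakLocations = as.integer(centers),
      baseCalls = paste(bases, collapse = ""),
      qualities = as.integer(qualities))
}
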