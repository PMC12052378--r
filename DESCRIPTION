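Package: sortSeqQC
Title: Quality Control and Index-Sort Integration for Sanger-Sequenced
    Immune Receptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality control of raw Sanger chromatograms (ABIF ".ab1")
    of immune-receptor (BCR/TCR) amplicons from index-sorted single
    cells, and integration with flow-cytometry index-sort fluorescence
    (FCS). Computes per-sequence quality metrics (modified-Mott trim
    positions, trimmed mean Phred quality, secondary-peak counts in an
    approximate CDR3 window), applies configurable pass/fail filters,
    derives data-driven thresholds by k-means clustering of quality
    parameters, joins per-well sequence QC with per-cell fluorescence,
    and writes FASTA, summary tables, QC reports and CDR3
    electropherograms. Includes a ground-truthed synthetic generator of
    ABIF and FCS fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    parallel,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
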