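Package: dualmap
Title: Dual-Mode Long-Read Mapping by Normalized Edit Distance Partitioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orchestrates a hybrid long-read mapping strategy for structural
    variant discovery: reads are first aligned with a fast mapper, each read's
    primary alignment is scored by its normalized edit distance (NM tag edit
    distance divided by aligned query length), the worst-aligned fraction of
    reads above a percentile cut-off (90th by default) is extracted back to
    FASTQ and realigned with a sensitive, convex-gap-penalty mapper, and the
    two record sets are merged into a single coordinate-sorted, indexed BAM
    ready for downstream structural variant calling. Includes a deterministic
    mock mapper backend and a synthetic-fixture generator (references with
    implanted structural variants, error-bearing simulated long reads,
    prescribed-edit-distance SAM files) so the whole pipeline is testable
    without external aligner binaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Rsamtools,
    GenomicAlignments,
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
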