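---
title: "Dual-mode long-read mapping by normalized edit distance partitioning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode long-read mapping by normalized edit distance partitioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualmap)
```

## The problem and the model

Long-read mappers trade speed against alignment quality at structural
variant (SV) breakpoints. Fast mappers built on two-piece affine gap
penalties place most reads well, but a minority of reads spanning large
insertions or deletions get forced into fragmented, high-edit-distance
alignments; mappers with convex gap costs recover those reads much better
but are roughly an order of magnitude slower. `dualmap` combines the two
regimes: it maps everything with the fast mapper, scores each read, and
pays the sensitive mapper's cost only for the reads that need it.

The per-read score is the **normalized edit distance**

$$E = \frac{e}{l},$$

where $e$ is the alignment's edit distance — the count of substitutions,
inserted and deleted bases, as stored in the SAM `NM` tag — and $l$ is the
alignment length. Only each read's **primary** record enters the profile:
secondary placements carry systematically larger edit distances and would
inflate the upper tail, and supplementary (split-read) segments are partial
by construction. Unmapped reads have no $E$; by default their records pass
through untouched (`realign_unmapped = TRUE` routes them to the sensitive
mapper instead, which can rescue reads the fast mapper gave up on).

Given the profile, a **percentile cut-off** $p$ (default 90) sets the
threshold: reads with $E$ strictly above the $p$-th percentile are
extracted back to FASTQ (reverse-strand primaries are
reverse-complemented, restoring sequencing orientation), realigned with
the sensitive mapper, and the two record sets are merged into one
coordinate-sorted, indexed BAM for downstream SV calling. At $p = 90$,
10% of reads are realigned; empirically that is where most of the
sensitive mapper's benefit concentrates, at a fraction of its cost.

## Numerical choices

**Denominator of $E$.** "Alignment length" admits two readings: the
aligned query length, or the full read length. We use the aligned query
length — the bases consumed by CIGAR `M`, `I`, `=` and `X` — because the
SAM specification defines `NM` over exactly that region, making $E$ a
well-defined per-base edit rate; with the full read length, heavily
soft-clipped reads would look artificially clean. Since soft clipping
concentrates at SV breakpoints, the choice matters there, so
`denominator = "read"` is exposed as an option and recorded in the stats
output.

**Percentile estimator.** The threshold is the *nearest-rank* order
statistic (rank $\lceil pn/100 \rceil$), not an interpolated quantile.
This guarantees the threshold is an observed $E$ value, so the strict rule
"realign iff $E > t$" has unambiguous tie semantics: reads tied with the
threshold stay in the keep-set, and the realigned fraction can never
exceed $(100-p)\%$. The two limits are exact identities and are tested as
such: $p = 100$ reproduces the fast mapper's BAM record for record, and
$p = 0$ (threshold sentinel strictly below every $E$) realigns every
profiled read.

**Missing `NM`.** When a mapped record lacks `NM`, the edit distance is
reconstructed from the MD tag plus CIGAR (MD mismatches + inserted +
deleted bases), with a structural cross-check that the MD's matched base
count equals the CIGAR's `M`/`=`/`X` total and its deletion run lengths
match the `D` total; inconsistency is an error, not a guess. Records with
neither tag cannot be profiled and raise a classed error.

**Fail-soft extraction.** A flagged read whose primary record is
hard-clipped or stores no sequence cannot be reconstituted into FASTQ.
Rather than aborting the run, such reads are reported, kept with the fast
mapper's records, and counted in the stats — hard-clipped primaries are a
mapper-dialect issue, not a user error.

**Conservation.** Routing is by read, never by record: all records of a
flagged read leave the keep stream together (the sensitive mapper
regenerates its own secondaries/supplementaries). Flagged reads the
sensitive mapper fails to place are emitted as unmapped records in the
final BAM, so primaries in equal primaries out for every run — an
invariant the suite checks at several cut-offs.

## Mapper backends

Both stages run behind one contract: a backend takes FASTQ + reference and
returns a BAM whose mapped records carry `NM` (or reconstructible MD). The
minimap2-style backend uses the long-read presets `map-ont` / `map-pb` /
`map-hifi` (with `--MD`); the NGMLR-style backend uses `-x ont` / `-x
pacbio`. A deterministic **mock backend** realizes a manifest mapping read
name to (position, CIGAR, NM, flags) — it performs no alignment, which is
exactly why end-to-end tests against it are exact and seed-free. The
substitutability of the contract is itself tested by running the whole
pipeline with (mock, mock).

## What the synthetic fixtures emulate — and what they do not

The fixture module generates, under a fixed seed and byte-reproducibly:
seeded references of stated GC content; alternate haplotypes with
implanted SVs (DEL/INS/INV/DUP/TRA, all ≥ 50 bp, non-overlapping, with
BED-like TSV and minimal VCF truth output); and long reads with an i.i.d.
error model — per-base substitutions at `sub_rate`, geometric-length
indels opened at `indel_rate`, with the realized per-read edit count
recorded exactly in the truth table. Defaults for desk-scale runs are a
single contig of tens of kilobases, a few hundred reads of 0.4–2 kb, and
error rates in the 2–10% range typical of ONT/PacBio CLR data; the
acceptance checks use 1,000-read profiles, 200–300-read pipeline runs and
10,000-record oracle sweeps, sizes at which every property is exact or
statistically stable.

This model deliberately omits what trained read simulators provide:
homopolymer-conditioned ONT errors, quality-value realism, chimeras, and
length distributions fit to real flow cells. Passing tests therefore
demonstrate the *mechanics* — profiling, thresholding, routing,
orientation handling, merging, conservation — not mapper accuracy on real
data. The exact-edit-count truth table is what makes the parameter-recovery
test sharp: reads simulated at substitution rate $s$ and mock-mapped
perfectly from the truth must profile with mean $E$ within three binomial
standard errors of $s$.

## Design decisions that were genuinely open

- **Secondary records of kept reads** are retained in the final BAM (the
  read was judged well-aligned; discarding its secondaries would
  second-guess the fast mapper), and the stats report says how many there
  are so downstream users can filter.
- **Unmapped reads** default to pass-through because the profile is
  defined over mapped primaries only; rescue via the sensitive mapper is
  opt-in.
- **Sorting happens once**, at merge time: backends emit unsorted BAM, and
  the merger coordinate-sorts and indexes, because the paper's downstream
  consumers (SV callers) require coordinate order and double sorting is
  wasted work.
- **MAPQ is not a filtering criterion**: it measures placement confidence
  in a region (repeats), not alignment-model misfit, which is what the
  edit distance captures.
- **No automatic percentile tuning**: the best cut-off varies with
  platform and coverage, and no principled selection rule exists without a
  truth set; `p` stays a user parameter with 90 as the shipped default.

## Limitations

Single-end long reads only (no pairing semantics, no CRAM); the in-memory
record table is suited to desk- and test-scale data, not a 60× human
genome, where the same algorithms should stream; the mock backend
validates plumbing, not alignment quality; and SV-calling accuracy
downstream of the merged BAM depends on the real external mappers and
caller, which this package orchestrates but does not reimplement. An
external-stack smoke script is provided under `inst/scripts/` for users
with minimap2, NGMLR and Sniffles installed.
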