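#' Configure a dual-mode mapping run
#'
#' @param reads FASTQ path (required unless `from_bam` is given).
#' @param reference FASTA path.
#' @param percentile cut-off `p` in `[0, 100]`; the worst-aligned
#'   `(100 - p)%` of reads (strictly above the nearest-rank threshold) are
#'   realigned. Default 90.
#' @param preset platform preset for both backends.
#' @param backend_fast,backend_sensitive [mapper_spec()]s for the first-pass
#'   and realignment mappers; default to minimap2 and NGMLR specs.
#' @param workdir directory for intermediates; created if missing.
#' @param threads threads handed to the backends.
#' @param keep_intermediates keep the step-1 BAM, split BAMs and
#'   realignment FASTQ under `workdir`.
#' @param realign_unmapped route unmapped reads into the realignment FASTQ
#'   instead of passing their records through.
#' @param from_bam pre-existing BAM/SAM with NM tags; skips the first
#'   mapping step.
#' @param denominator denominator of the normalized edit distance
#'   (`"aligned"` or `"read"`; see [normalized_edit_distance()]).
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(reads = NULL, reference, percentile = 90,
                            preset = c("ont", "pacbio_clr", "pacbio_hifi"),
                            backend_fast = NULL, backend_sensitive = NULL,
                            workdir = tempfile("dualmap_"), threads = 1L,
                            keep_intermediates = FALSE,
                            realign_unmapped = FALSE, from_bam = NULL,
                            denominator = c("aligned", "read")) {
  preset <- match.arg(preset)
  denominator <- match.arg(denominator)
  if (!is.numeric(percentile) || length(percentile) != 1 ||
      percentile < 0 || percentile > 100)
    dm_stop("percentile must be a single value in [0, 100]", "validation")
  if (is.null(reads) && is.null(from_bam))
    dm_stop("either reads or from_bam is required", "validation")
  if (is.null(backend_fast))
    backend_fast <- mapper_spec("minimap2", preset = preset, threads = threads)
  if (is.null(backend_sensitive))
    backend_sensitive <- mapper_spec("ngmlr", preset = preset, threads = threads)
  structure(list(reads = reads, reference = reference, percentile = percentile,
                 preset = preset, backend_fast = backend_fast,
                 backend_sensitive = backend_sensitive, workdir = workdir,
                 threads = as.integer(threads),
                 keep_intermediates = keep_intermediates,
                 realign_unmapped = realign_unmapped, from_bam = from_bam,
                 denominator = denominator),
            class = "pipeline_config")
}

#' Run the dual-mode mapping pipeline
#'
#' Executes the four stages end to end: (1) map all reads with the fast
#' backend (or load `from_bam`); (2) profile each read's primary alignment
#' by normalized edit distance and take the percentile cut-off; (3) extract
#' the flagged reads to FASTQ and realign them with the sensitive backend;
#' (4) merge the kept records with the realignments into one
#' coordinate-sorted, indexed BAM, verified against the partition. Flagged
#' reads the sensitive mapper leaves unplaced are carried as unmapped
#' records rather than dropped, so read counts are conserved.
#'
#' @param config a [pipeline_config()].
#' @param out_bam final BAM path (default `final.bam` under the workdir).
#' @return a `pipeline_run`: list with `bam` (final path) and `stats` (a
#'   `stats_report`, also written as JSON next to the BAM).
#' @export
run_pipeline <- function(config, out_bam = file.path(config$workdir, "final.bam")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  timings <- c()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    r <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    r
  }

  # stage 1: first-pass mapping (or user-supplied BAM)
  step1_bam <- file.path(config$workdir, "step1.bam")
  fast_version <- NA_character_
  if (is.null(config$from_bam)) {
    res <- tick("map_fast", run_mapper(config$backend_fast, config$reads,
                                       config$reference, step1_bam))
    fast_version <- res$version
    n_reads <- res$n_input_reads
    aln <- read_alignments(step1_bam)
  } else {
    aln <- tick("map_fast", read_alignments(config$from_bam))
    n_reads <- length(unique(aln$records$qname))
    fast_version <- "user-supplied"
  }

  # stage 2: profile + percentile cut-off + partition
  prof <- NULL
  part <- tick("profile", {
    # expr is a promise evaluated in this frame, so plain <- lands here
    prof <- build_profile(aln, source_label = config$backend_fast$name,
                          denominator = config$denominator)
    if (nrow(prof) == 0) dm_stop("no primary mapped records to profile", "empty_profile")
    thr <- percentile_threshold(prof, config$percentile)
    partition_reads(prof, thr)
  })

  # stage 3: split, extract, realign
  split <- tick("split_extract", {
    s <- split_alignments(aln, part,
                          unmapped_policy = if (config$realign_unmapped) "realign" else "keep")
    ex <- extract_reads(s$realign)
    if (length(ex$unextractable)) {
      # fail-soft: unextractable reads stay with the fast mapper's records
      back <- s$realign$records$qname %in% ex$unextractable
      s$keep$records <- rbind(s$keep$records,
                              s$realign$records[back, , drop = FALSE])
      s$realign$records <- s$realign$records[!back, , drop = FALSE]
    }
    list(keep = s$keep, reads = ex$reads, unextractable = ex$unextractable)
  })
  keep_bam <- file.path(config$workdir, "keep.bam")
  write_bam(split$keep, keep_bam, sort = FALSE, index = FALSE)
  realign_fq <- file.path(config$workdir, "realign.fastq")
  write_fastq(split$reads, realign_fq)

  sens_version <- NA_character_
  realigned_bam <- NULL
  if (nrow(split$reads) > 0) {
    realigned_bam <- file.path(config$workdir, "realigned.bam")
    res2 <- tick("map_sensitive",
                 run_mapper(config$backend_sensitive, realign_fq,
                            config$reference, realigned_bam))
    sens_version <- res2$version
    # conservation: flagged reads the sensitive mapper dropped entirely are
    # re-emitted as unmapped records
    re <- read_alignments(realigned_bam)
    missing <- setdiff(split$reads$name, unique(re$records$qname))
    if (length(missing)) {
      i <- match(missing, split$reads$name)
      re$records <- rbind(re$records, data.frame(
        qname = missing, flag = FLAG_UNMAPPED, rname = NA_character_,
        pos = NA_integer_, mapq = 0L, cigar = NA_character_,
        seq = split$reads$seq[i], qual = split$reads$qual[i],
        nm = NA_integer_, md = NA_character_, stringsAsFactors = FALSE))
      write_bam(re, realigned_bam, sort = FALSE, index = FALSE)
    }
  } else {
    timings[["map_sensitive"]] <- 0
  }

  # stage 4: merge + verify
  keep_univ <- unique(split$keep$records$qname)
  plan <- merge_plan(keep_bam, realigned_bam,
                     expected_keep_names = keep_univ,
                     expected_realign_names = setdiff(split$reads$name, keep_univ),
                     out_path = out_bam)
  tick("merge", merge_bams(plan))
  violations <- tick("verify", verify_merge(out_bam, plan))
  if (length(violations))
    dm_stop(paste("merge verification failed:", paste(violations, collapse = "; ")),
            "validation")

  final_prof <- build_profile(read_alignments(out_bam), source_label = "final",
                              denominator = config$denominator)
  n_realigned <- nrow(split$reads)
  stats <- structure(list(
    n_reads = n_reads,
    n_profiled = part$n_eligible,
    n_realigned = n_realigned,
    realigned_fraction = n_realigned / part$n_eligible,
    threshold = part$threshold,
    percentile = config$percentile,
    n_unextractable = length(split$unextractable),
    denominator = config$denominator,
    summary_before = summarize_profile(prof),
    summary_after = summarize_profile(final_prof),
    per_stage_seconds = as.list(timings),
    backend_versions = list(fast = fast_version, sensitive = sens_version)
  ), class = "stats_report")
  jsonlite::write_json(stats_to_list(stats),
                       paste0(sub("\\.bam$", "", out_bam), ".stats.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  if (!config$keep_intermediates)
    unlink(c(step1_bam, keep_bam, realigned_bam, realign_fq))
  structure(list(bam = out_bam, stats = stats), class = "pipeline_run")
}

stats_to_list <- function(s) {
  out <- unclass(s)
  out$threshold <- if (is.infinite(out$threshold)) "below_min" else out$threshold
  out$summary_before <- unclass(out$summary_before)
  out$summary_after <- unclass(out$summary_after)
  out
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf(
    paste0("<stats_report>\n  reads: %d (profiled %d, unprofiled %d)\n",
           "  realigned: %d (%.1f%% at p=%g, threshold %s)\n",
           "  median E before %.4f -> after %.4f\n"),
    x$n_reads, x$n_profiled, max(0L, x$n_reads - x$n_profiled),
    x$n_realigned, 100 * x$realigned_fraction, x$percentile,
    format(x$threshold, digits = 4),
    x$summary_before$median_E, x$summary_after$median_E))
  cat("  stage seconds:",
      paste(sprintf("%s=%.2f", names(x$per_stage_seconds),
                    unlist(x$per_stage_seconds)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> final BAM: %s\n", x$bam))
  print(x$stats)
  cat(sprintf("suggested downstream call: sniffles --input %s --vcf calls.vcf\n",
              x$bam))
  invisible(x)
}

#' Compare E distributions across mapping results
#'
#' Builds profiles for the fast mapper's output, the sensitive mapper's
#' output and the merged result, and reports their distribution summaries
#' side by side — the fixture-scale analogue of comparing the three
#' mappers' normalized edit distance distributions genome-wide. Expect the
#' merged median at or below the fast mapper's.
#'
#' @param bam_a,bam_b,bam_final paths (SAM or BAM); `bam_b` may be `NULL`.
#' @param bins histogram bins.
#' @param denominator see [normalized_edit_distance()].
#' @return a `profile_comparison`: named list of `ed_summary` objects plus a
#'   `medians` data.frame.
#' @export
compare_profiles <- function(bam_a, bam_b = NULL, bam_final, bins = 50,
                             denominator = c("aligned", "read")) {
  denominator <- match.arg(denominator)
  mk <- function(path, label) {
    if (is.null(path)) return(NULL)
    build_profile(read_alignments(path), source_label = label,
                  denominator = denominator)
  }
  profs <- Filter(Negate(is.null), list(
    fast = mk(bam_a, "fast"), sensitive = mk(bam_b, "sensitive"),
    final = mk(bam_final, "final")))
  universes <- lapply(profs, function(p) p$read_name)
  common <- Reduce(intersect, universes)
  if (length(common) == 0 && length(profs) > 1)
    dm_warn("profiles share no read names; comparison is across disjoint sets",
            "disjoint_universe")
  sums <- lapply(profs, summarize_profile, bins = bins)
  medians <- data.frame(
    source = names(sums),
    n = vapply(sums, `[[`, 0, "n"),
    median_E = vapply(sums, `[[`, 0, "median_E"),
    q1 = vapply(sums, `[[`, 0, "q1"),
    q3 = vapply(sums, `[[`, 0, "q3"), row.names = NULL)
  structure(list(summaries = sums, medians = medians),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat("<profile_comparison>\n")
  print(x$medians, row.names = FALSE)
  invisible(x)
}
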