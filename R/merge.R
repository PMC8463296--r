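#' Plan a merge of keep-set and realigned alignments
#'
#' @param keep_bam BAM holding the fast mapper's records for kept reads.
#' @param realigned_bam BAM holding the sensitive mapper's records for
#'   flagged reads (may be empty at `p = 100`).
#' @param expected_keep_names,expected_realign_names read-name sets the two
#'   inputs are expected to cover (must be disjoint).
#' @param out_path path for the final coordinate-sorted, indexed BAM.
#' @return a `merge_plan`.
#' @export
merge_plan <- function(keep_bam, realigned_bam, expected_keep_names,
                       expected_realign_names, out_path) {
  if (length(intersect(expected_keep_names, expected_realign_names)))
    dm_stop("keep and realign name sets overlap", "cross_contamination")
  structure(list(keep_bam = keep_bam, realigned_bam = realigned_bam,
                 expected_keep_names = expected_keep_names,
                 expected_realign_names = expected_realign_names,
                 out_path = out_path),
            class = "merge_plan")
}

same_sq <- function(a, b) {
  nrow(a) == nrow(b) && all(a$name == b$name) && all(a$length == b$length)
}

#' Merge the keep-set with the realignments into the final BAM
#'
#' Concatenates every record of both inputs, coordinate-sorts, indexes,
#' and extends the `@PG` chain with both mappers' programs plus this tool.
#' Fails if the reference dictionaries differ, if any read name occurs in
#' both inputs, or if any read would end up with more than one primary
#' record.
#'
#' @param plan a [merge_plan()].
#' @return the final BAM path, invisibly.
#' @export
merge_bams <- function(plan) {
  keep <- read_alignments(plan$keep_bam)
  re <- if (!is.null(plan$realigned_bam) && file.exists(plan$realigned_bam))
    read_alignments(plan$realigned_bam)
  else sam_set(empty_records(), keep$header)
  if (!same_sq(keep$header$sq, re$header$sq) && nrow(re$records) > 0)
    dm_stop("reference dictionaries (@SQ) differ between merge inputs",
            "header_mismatch")
  both <- intersect(unique(keep$records$qname), unique(re$records$qname))
  if (length(both))
    dm_stop(sprintf("read(s) present in both merge inputs: %s",
                    paste(utils::head(both, 5), collapse = ", ")),
            "cross_contamination")
  rec <- rbind(keep$records, re$records)
  cl <- classify_alignment(rec$flag)
  prim_names <- rec$qname[cl == "primary"]
  if (anyDuplicated(prim_names))
    dm_stop("a read has more than one primary record after merging",
            "duplicate_primary")
  hdr <- keep$header
  hdr$pg <- unique(c(keep$header$pg, re$header$pg))
  hdr <- append_pg(hdr, "dualmap", "dualmap",
                   sprintf("merge_bams keep=%s realigned=%s",
                           basename(plan$keep_bam),
                           basename(plan$realigned_bam %||% "none")))
  write_bam(sam_set(rec, hdr), plan$out_path, sort = TRUE, index = TRUE)
  invisible(plan$out_path)
}

#' Verify a merged BAM against its plan
#'
#' Report-based validation: coordinate sortedness (header flag plus an
#' adjacent-record scan), index presence and validity, at most one primary
#' record per read, and read-name equality with the plan's expected sets.
#'
#' @param final_bam the merged BAM.
#' @param plan the [merge_plan()] it was produced from.
#' @return character vector of violations; empty means pass.
#' @export
verify_merge <- function(final_bam, plan) {
  v <- character()
  if (!file.exists(final_bam)) return("final BAM missing")
  x <- read_alignments(final_bam)
  rec <- x$records
  if (!identical(x$header$so, "coordinate"))
    v <- c(v, "header does not declare coordinate sort order")
  mapped <- rec[!is.na(rec$pos), , drop = FALSE]
  if (nrow(mapped) > 1) {
    ord <- order(match(mapped$rname, x$header$sq$name), mapped$pos)
    if (!identical(ord, seq_len(nrow(mapped))))
      v <- c(v, "not coordinate-sorted")
  }
  bai <- paste0(final_bam, ".bai")
  if (!file.exists(bai)) {
    v <- c(v, "index missing")
  } else {
    ok <- tryCatch({ Rsamtools::idxstatsBam(final_bam); TRUE },
                   error = function(e) FALSE)
    if (!ok) v <- c(v, "index invalid")
  }
  cl <- classify_alignment(rec$flag)
  pn <- rec$qname[cl == "primary"]
  if (anyDuplicated(pn))
    v <- c(v, sprintf("duplicate primary record(s): %s",
                      paste(unique(pn[duplicated(pn)]), collapse = ", ")))
  expected <- sort(unique(c(plan$expected_keep_names, plan$expected_realign_names)))
  got <- sort(unique(rec$qname))
  missing <- setdiff(expected, got)
  extra <- setdiff(got, expected)
  if (length(missing))
    v <- c(v, sprintf("missing read(s): %s", paste(missing, collapse = ", ")))
  if (length(extra))
    v <- c(v, sprintf("unexpected read(s): %s", paste(extra, collapse = ", ")))
  v
}
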