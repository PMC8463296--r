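#' Partition profiled reads around a threshold
#'
#' A read is flagged for realignment iff its normalized edit distance is
#' strictly greater than the threshold; reads tied with the threshold stay
#' in the keep-set, so at the nearest-rank cut-off the realigned fraction
#' never exceeds `(100 - p)%`.
#'
#' @param profile an `ed_profile` from [build_profile()].
#' @param threshold value from [percentile_threshold()] (or
#'   [SENTINEL_BELOW_MIN]).
#' @return a `partition_result`: list with `threshold`, `keep_names`,
#'   `realign_names`, `n_eligible`, `n_unmapped`.
#' @export
partition_reads <- function(profile, threshold) {
  flag <- profile$E > threshold
  structure(list(
    threshold = threshold,
    keep_names = profile$read_name[!flag],
    realign_names = profile$read_name[flag],
    n_eligible = nrow(profile),
    n_unmapped = attr(profile, "n_unmapped") %||% 0L
  ), class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf(
    "<partition_result> %d profiled reads: keep %d, realign %d (threshold %s); %d unmapped\n",
    x$n_eligible, length(x$keep_names), length(x$realign_names),
    format(x$threshold, digits = 4), x$n_unmapped))
  invisible(x)
}

#' Split an alignment set into keep-records and realignment groups
#'
#' Routing is by read, not by record: all records (primary, secondary,
#' supplementary) of a flagged read leave the keep stream together, since
#' the sensitive mapper will regenerate its own placements for those reads.
#' Unmapped records follow `unmapped_policy`: pass through to the keep
#' stream unchanged (default) or join the realignment set.
#'
#' @param x a [sam_set()].
#' @param partition a `partition_result` from [partition_reads()].
#' @param unmapped_policy `"keep"` or `"realign"`.
#' @return list with `keep` and `realign`, both `sam_set`s sharing the
#'   input header. Errors with `dualmap_orphan_record` if a mapped record's
#'   read name was never profiled.
#' @export
split_alignments <- function(x, partition, unmapped_policy = c("keep", "realign")) {
  unmapped_policy <- match.arg(unmapped_policy)
  rec <- x$records
  cl <- classify_alignment(rec$flag)
  universe <- c(partition$keep_names, partition$realign_names)
  orphan <- cl != "unmapped" & !(rec$qname %in% universe)
  if (any(orphan))
    dm_stop(sprintf("mapped record(s) never profiled: %s",
                    paste(unique(rec$qname[orphan]), collapse = ", ")),
            "orphan_record")
  to_realign <- rec$qname %in% partition$realign_names & cl != "unmapped"
  if (unmapped_policy == "realign")
    to_realign <- to_realign | cl == "unmapped"
  list(keep = sam_set(rec[!to_realign, , drop = FALSE], x$header),
       realign = sam_set(rec[to_realign, , drop = FALSE], x$header))
}

# reverse a quality string; revcomp via Biostrings
revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}
rev_chr <- function(s) {
  vapply(strsplit(s, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Extract realignment reads back to FASTQ
#'
#' Takes the primary record of each flagged read and emits one FASTQ record
#' in original sequencing orientation: primaries stored on the reverse
#' strand are reverse-complemented (and their qualities reversed) first,
#' undoing the SAM storage convention. Reads whose primary record carries
#' hard clips or no sequence (`*`) cannot be reconstituted; these are
#' reported and the caller retains them in the keep stream (fail-soft).
#'
#' @param realign a `sam_set` holding the flagged reads' records (from
#'   [split_alignments()]).
#' @return list with `reads` (data.frame `name`, `seq`, `qual`, one row per
#'   extractable read) and `unextractable` (character vector of read names).
#' @export
extract_reads <- function(realign) {
  rec <- realign$records
  cl <- classify_alignment(rec$flag)
  prim <- rec[cl == "primary", , drop = FALSE]
  # unmapped reads routed here (realign_unmapped) have their sequence on
  # the record as stored; treat them like forward primaries
  unm <- rec[cl == "unmapped" & !(rec$qname %in% prim$qname), , drop = FALSE]
  if (nrow(unm)) { unm$cigar <- "" ; prim <- rbind(prim, unm) }
  bad <- prim$seq == "*" |
    (!is.na(prim$cigar) & grepl("H", prim$cigar, fixed = TRUE))
  out <- prim[!bad, , drop = FALSE]
  is_rev <- bitwAnd(out$flag, FLAG_REVERSE) != 0L
  seqs <- out$seq
  quals <- out$qual
  if (any(is_rev)) {
    seqs[is_rev] <- revcomp_chr(seqs[is_rev])
    quals[is_rev] <- rev_chr(quals[is_rev])
  }
  quals[quals == "*"] <- vapply(nchar(seqs[quals == "*"]),
                                function(n) strrep("I", n), "")
  list(reads = data.frame(name = out$qname, seq = seqs, qual = quals,
                          stringsAsFactors = FALSE),
       unextractable = prim$qname[bad])
}

#' Write reads as 4-line FASTQ (Phred+33)
#' @param reads data.frame with `name`, `seq`, `qual` (as from
#'   [extract_reads()]).
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  s <- Biostrings::DNAStringSet(reads$seq)
  names(s) <- reads$name
  Biostrings::writeXStringSet(s, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ path.
#' @return data.frame with `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(name = character(), seq = character(), qual = character(),
                      stringsAsFactors = FALSE))
  s <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(name = sub("\\s.*$", "", names(s)),
             seq = as.character(s),
             qual = as.character(S4Vectors::mcols(s)$qualities),
             stringsAsFactors = FALSE)
}
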