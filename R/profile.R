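#' Normalized edit distance of mapped records
#'
#' `E = e / l`: the edit distance `e` (NM tag, reconstructed from MD+CIGAR
#' when absent) over the alignment length `l`. The default denominator is
#' the aligned query length (CIGAR M/I/`=`/X), so that `E` is an edit rate
#' over exactly the region in which NM counts edits; `denominator = "read"`
#' uses the full read length (aligned length plus soft clips) instead.
#'
#' @param records data.frame of mapped records (columns `nm`, `md`, `cigar`).
#' @param denominator `"aligned"` (default) or `"read"`.
#' @return numeric vector of normalized edit distances.
#' @export
normalized_edit_distance <- function(records, denominator = c("aligned", "read")) {
  denominator <- match.arg(denominator)
  e <- edit_distance_of(records$nm, records$md, records$cigar)
  l <- if (denominator == "aligned") query_alignment_length(records$cigar)
       else cigar_query_width(records$cigar)  # includes soft clips
  e / l
}

#' Build a per-read normalized edit distance profile
#'
#' One entry per read, computed from that read's primary mapped record only.
#' Secondary records are excluded because they carry systematically larger
#' edit distances than the primary placement; supplementary (split-read)
#' segments and unmapped records contribute nothing either.
#'
#' @param x a [sam_set()] or its records data.frame.
#' @param source_label which mapper produced the alignments (recorded in the
#'   profile and its exports).
#' @param denominator passed to [normalized_edit_distance()].
#' @param include_supplementary also profile supplementary segments as extra
#'   entries keyed by read name (off by default; primary-only is the
#'   documented behaviour and required for partitioning).
#' @return an `ed_profile`: data.frame with columns `read_name`, `E`, plus
#'   attributes `source_label`, `denominator`, `n_unmapped`.
#' @export
build_profile <- function(x, source_label = "unknown",
                          denominator = c("aligned", "read"),
                          include_supplementary = FALSE) {
  denominator <- match.arg(denominator)
  rec <- if (inherits(x, "sam_set")) x$records else x
  cl <- classify_alignment(rec$flag)
  prim <- rec[cl == "primary", , drop = FALSE]
  if (anyDuplicated(prim$qname))
    dm_stop(sprintf("duplicate primary record(s) for read(s): %s",
                    paste(unique(prim$qname[duplicated(prim$qname)]), collapse = ", ")),
            "duplicate_primary")
  keep <- prim
  if (include_supplementary)
    keep <- rbind(prim, rec[cl == "supplementary", , drop = FALSE])
  E <- if (nrow(keep)) normalized_edit_distance(keep, denominator) else numeric()
  prof <- data.frame(read_name = keep$qname, E = E, stringsAsFactors = FALSE)
  prof <- prof[order(prof$read_name), , drop = FALSE]
  rownames(prof) <- NULL
  structure(prof, class = c("ed_profile", "data.frame"),
            source_label = source_label, denominator = denominator,
            n_unmapped = sum(cl == "unmapped"))
}

#' @export
print.ed_profile <- function(x, ...) {
  cat(sprintf("<ed_profile> %d reads from '%s' (denominator: %s)\n",
              nrow(x), attr(x, "source_label"), attr(x, "denominator")))
  if (nrow(x))
    cat(sprintf("  E: median %.4f, range [%.4f, %.4f]\n",
                stats::median(x$E), min(x$E), max(x$E)))
  invisible(x)
}

#' Percentile cut-off over a profile (nearest-rank estimator)
#'
#' Sorts the E values ascending and returns the value at rank
#' `ceiling(p * n / 100)`. The nearest-rank estimator guarantees the
#' threshold is an observed E value, which makes the strict flagging rule
#' `E > threshold` unambiguous: ties at the threshold stay in the keep-set,
#' so the realigned fraction never exceeds `(100 - p)%`. At `p = 0` the
#' sentinel [SENTINEL_BELOW_MIN] (strictly below every E) is returned and
#' every read is flagged.
#'
#' @param profile an `ed_profile` from [build_profile()].
#' @param p percentile in `[0, 100]`; default 90, i.e. the worst-aligned 10%
#'   of reads are routed to the sensitive mapper.
#' @return the threshold (a numeric scalar, possibly `-Inf`).
#' @export
percentile_threshold <- function(profile, p = 90) {
  stopifnot(length(p) == 1, p >= 0, p <= 100)
  n <- nrow(profile)
  if (n == 0L) dm_stop("cannot take a percentile of an empty profile", "empty_profile")
  if (p == 0) return(SENTINEL_BELOW_MIN)
  k <- ceiling(p * n / 100)
  sort(profile$E)[k]
}

#' Summarize a profile's E distribution
#'
#' Median and quartiles by linear interpolation; an equal-width histogram
#' over `[0, max(E)]` with half-open bins (the last bin closed so the
#' maximum is counted).
#'
#' @param profile an `ed_profile`.
#' @param bins number of histogram bins (>= 1).
#' @return an `ed_summary` list: `n`, `median_E`, `q1`, `q3`, `histogram`
#'   (data.frame `bin_left`, `bin_right`, `count`), `source_label`.
#' @export
summarize_profile <- function(profile, bins = 50) {
  stopifnot(bins >= 1)
  n <- nrow(profile)
  if (n == 0L) dm_stop("cannot summarize an empty profile", "empty_profile")
  E <- profile$E
  q <- stats::quantile(E, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  hi <- max(E)
  if (hi == 0) hi <- 1e-9  # degenerate all-zero profile still gets one bin span
  breaks <- seq(0, hi, length.out = bins + 1)
  idx <- findInterval(E, breaks, rightmost.closed = TRUE, left.open = FALSE)
  idx[idx < 1L] <- 1L
  counts <- tabulate(idx, nbins = bins)
  structure(list(
    n = n, median_E = q[2], q1 = q[1], q3 = q[3],
    histogram = data.frame(bin_left = breaks[-length(breaks)],
                           bin_right = breaks[-1], count = counts),
    source_label = attr(profile, "source_label") %||% "unknown"
  ), class = "ed_summary")
}

#' @export
print.ed_summary <- function(x, ...) {
  cat(sprintf("<ed_summary> '%s': n=%d, median E=%.4f, IQR [%.4f, %.4f]\n",
              x$source_label, x$n, x$median_E, x$q1, x$q3))
  invisible(x)
}

#' Export a profile as TSV
#'
#' Columns: `read_name`, `E`, `source_label`.
#' @param profile an `ed_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  out <- data.frame(read_name = profile$read_name, E = profile$E,
                    source_label = attr(profile, "source_label") %||% "unknown")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a distribution summary as JSON
#' @param summary an `ed_summary`.
#' @param path output path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
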