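# SAM flag bits (SAM v1 spec)
FLAG_PAIRED        <- 0x1L
FLAG_UNMAPPED      <- 0x4L
FLAG_REVERSE       <- 0x10L
FLAG_SECONDARY     <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

#' Construct a set of alignment records
#'
#' The package's in-memory representation of SAM/BAM content: a plain
#' `data.frame` of records plus a parsed header. Positions are 0-based
#' internally and converted to SAM's 1-based convention only at I/O
#' boundaries. `nm` and `md` hold the NM (edit distance) and MD optional
#' tags, `NA` when absent.
#'
#' @param records data.frame with columns `qname`, `flag`, `rname`, `pos`
#'   (0-based, `NA` for unmapped), `mapq`, `cigar`, `seq`, `qual`, `nm`, `md`.
#' @param header a header as built by [sam_header()].
#' @return an object of class `sam_set`.
#' @export
sam_set <- function(records, header) {
  needed <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
              "seq", "qual", "nm", "md")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    dm_stop(paste("records missing columns:", paste(miss, collapse = ", ")),
            "malformed_record")
  records$flag <- as.integer(records$flag)
  records$pos <- as.integer(records$pos)
  records$nm <- as.integer(records$nm)
  rownames(records) <- NULL
  structure(list(records = records, header = header), class = "sam_set")
}

#' @export
print.sam_set <- function(x, ...) {
  cat(sprintf("<sam_set> %d records on %d reference sequence(s)\n",
              nrow(x$records), nrow(x$header$sq)))
  cl <- classify_alignment(x$records$flag)
  print(table(cl))
  invisible(x)
}

#' Build a SAM header
#'
#' @param sq data.frame with columns `name` and `length` (reference dictionary).
#' @param pg character vector of `@PG` lines (tab-separated, starting `@PG`).
#' @param so sort order recorded in `@HD` (`unsorted`, `coordinate`, `queryname`).
#' @param other further verbatim header lines (e.g. `@RG`, `@CO`).
#' @export
sam_header <- function(sq, pg = character(), so = "unsorted", other = character()) {
  stopifnot(is.data.frame(sq), all(c("name", "length") %in% names(sq)))
  sq$name <- as.character(sq$name)
  sq$length <- as.integer(sq$length)
  structure(list(sq = sq, pg = pg, so = so, other = other),
            class = "sam_header")
}

header_lines <- function(h) {
  c(sprintf("@HD\tVN:1.6\tSO:%s", h$so),
    sprintf("@SQ\tSN:%s\tLN:%d", h$sq$name, h$sq$length),
    h$pg, h$other)
}

# append a @PG record, chaining PP to the previous @PG's ID
append_pg <- function(header, id, pn, cl) {
  prev <- header$pg
  pp <- if (length(prev)) {
    last <- prev[length(prev)]
    sub("^.*\\bID:([^\t]+).*$", "\\1", last)
  } else NULL
  line <- sprintf("@PG\tID:%s\tPN:%s%s\tCL:%s", id, pn,
                  if (is.null(pp)) "" else sprintf("\tPP:%s", pp), cl)
  # IDs must be unique within a header
  ids <- sub("^.*\\bID:([^\t]+).*$", "\\1", prev)
  if (id %in% ids) line <- sub(sprintf("ID:%s", id),
                               sprintf("ID:%s.%d", id, length(prev)), line)
  header$pg <- c(prev, line)
  header
}

#' Classify alignment records by SAM flag
#'
#' Unmapped takes precedence; the secondary and supplementary bits are
#' mutually exclusive in the "primary" sense — a record is primary only
#' when neither is set.
#'
#' @param flag integer vector of SAM flags.
#' @return factor with levels `primary`, `secondary`, `supplementary`,
#'   `unmapped`.
#' @export
classify_alignment <- function(flag) {
  flag <- as.integer(flag)
  out <- rep("primary", length(flag))
  out[bitwAnd(flag, FLAG_SUPPLEMENTARY) != 0L] <- "supplementary"
  out[bitwAnd(flag, FLAG_SECONDARY) != 0L] <- "secondary"
  out[bitwAnd(flag, FLAG_UNMAPPED) != 0L] <- "unmapped"
  factor(out, levels = c("primary", "secondary", "supplementary", "unmapped"))
}

# ---- CIGAR arithmetic (delegated to GenomicAlignments) ----

#' Aligned query length of records
#'
#' Number of query bases consumed by the aligned portion of the CIGAR:
#' the M, I, `=` and X operations. Soft and hard clips are excluded, as are
#' D/N/P which consume no query. This is the denominator `l` of the
#' normalized edit distance `E = e / l`.
#'
#' @param cigar character vector of CIGAR strings.
#' @return integer vector; errors with class `dualmap_empty_alignment` if a
#'   CIGAR contains no query-consuming aligned operation.
#' @export
query_alignment_length <- function(cigar) {
  tab <- GenomicAlignments::cigarOpTable(cigar)
  len <- as.integer(tab[, "M"] + tab[, "I"] + tab[, "="] + tab[, "X"])
  if (any(len == 0L))
    dm_stop("CIGAR has no query-consuming aligned operation (M/I/=/X)",
            "empty_alignment")
  len
}

# total query bases a CIGAR consumes (M,I,S,=,X) — must equal seq length
cigar_query_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
}

# ---- MD-tag reconstruction of the edit distance ----

# Parse an MD tag into its token stream. Returns list(match_total,
# n_mismatch, del_total) or NULL on syntactically invalid MD.
parse_md <- function(md) {
  # SAM spec: MD matches [0-9]+(([A-Z]|\^[A-Z]+)[0-9]+)*
  if (!grepl("^[0-9]+(([A-Z]|\\^[A-Z]+)[0-9]+)*$", md, perl = TRUE))
    return(NULL)
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  nums <- suppressWarnings(as.integer(toks[grepl("^[0-9]+$", toks)]))
  dels <- toks[startsWith(toks, "^")]
  mism <- toks[grepl("^[A-Z]$", toks)]
  list(match_total = sum(nums),
       n_mismatch = length(mism),
       del_total = sum(nchar(dels) - 1L))
}

#' Edit distance of mapped records
#'
#' Returns the NM-tag value where present. When NM is absent it is
#' reconstructed from the MD tag and CIGAR as
#' (mismatches in MD) + (total inserted bases) + (total deleted bases),
#' which is exactly what mappers store in NM. The reconstruction is checked
#' structurally against the CIGAR: the MD's matched+mismatched base count
#' must equal the aligned reference-matching length (M + `=` + X) and its
#' deletion length must equal the CIGAR's D total.
#'
#' @param nm integer vector (NA where the tag is absent).
#' @param md character vector of MD tags (NA where absent).
#' @param cigar character vector of CIGAR strings.
#' @return integer vector of edit distances. Errors: `dualmap_missing_evidence`
#'   when both NM and MD are absent; `dualmap_malformed_tag` when MD and CIGAR
#'   disagree structurally.
#' @export
edit_distance_of <- function(nm, md, cigar) {
  nm <- as.integer(nm)
  need <- which(is.na(nm))
  if (!length(need)) return(nm)
  if (any(is.na(md[need])))
    dm_stop("edit distance unobtainable: NM and MD both absent", "missing_evidence")
  tab <- GenomicAlignments::cigarOpTable(cigar[need])
  for (j in seq_along(need)) {
    i <- need[j]
    p <- parse_md(md[i])
    if (is.null(p)) dm_stop(sprintf("malformed MD tag '%s'", md[i]), "malformed_tag")
    m_len <- tab[j, "M"] + tab[j, "="] + tab[j, "X"]
    if (p$match_total + p$n_mismatch != m_len || p$del_total != tab[j, "D"])
      dm_stop(sprintf("MD tag '%s' inconsistent with CIGAR '%s'", md[i], cigar[i]),
              "malformed_tag")
    nm[i] <- p$n_mismatch + tab[j, "I"] + tab[j, "D"]
  }
  nm
}

# ---- SAM/BAM I/O ----

#' Read alignments from SAM or BAM into a `sam_set`
#'
#' SAM text is converted with `Rsamtools::asBam` first; records, the NM and
#' MD tags and the header dictionary are pulled through `Rsamtools::scanBam`.
#'
#' @param path path to a `.sam` or `.bam` file.
#' @return a [sam_set()].
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) dm_stop(paste("no such file:", path), "io")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             indexDestination = FALSE, overwrite = TRUE))
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]
  sq <- data.frame(name = names(hdr$targets),
                   length = as.integer(unname(hdr$targets)),
                   stringsAsFactors = FALSE)
  txt <- hdr$text
  pg <- vapply(txt[names(txt) == "@PG"], function(x) paste(c("@PG", x), collapse = "\t"), "")
  so <- "unsorted"
  hd <- txt[names(txt) == "@HD"]
  if (length(hd)) {
    sofield <- grep("^SO:", hd[[1]], value = TRUE)
    if (length(sofield)) so <- sub("^SO:", "", sofield[1])
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"),
    tag = c("NM", "MD"))
  res <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(res$qname)
  rec <- data.frame(
    qname = as.character(res$qname),
    flag = as.integer(res$flag),
    rname = as.character(res$rname),
    pos = as.integer(res$pos) - 1L,  # to 0-based
    mapq = as.integer(res$mapq),
    cigar = as.character(res$cigar),
    seq = if (n) as.character(res$seq) else character(),
    qual = if (n) as.character(res$qual) else character(),
    nm = as.integer(res$tag$NM %||% rep(NA_integer_, n)),
    md = as.character(res$tag$MD %||% rep(NA_character_, n)),
    stringsAsFactors = FALSE
  )
  if (n) {
    rec$seq[rec$seq == ""] <- "*"
    rec$qual[rec$qual == ""] <- "*"
    rec$mapq[is.na(rec$mapq)] <- 0L
    unm <- bitwAnd(rec$flag, FLAG_UNMAPPED) != 0L
    rec$cigar[unm] <- NA_character_
  }
  sam_set(rec, sam_header(sq, pg = unname(pg), so = so))
}

#' Write a `sam_set` as SAM text
#'
#' @param x a [sam_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(x, path) {
  r <- x$records
  opt <- character(nrow(r))
  if (nrow(r)) {
    opt <- ifelse(is.na(r$nm), "", sprintf("\tNM:i:%d", r$nm))
    opt <- paste0(opt, ifelse(is.na(r$md), "", sprintf("\tMD:Z:%s", r$md)))
  }
  body <- if (nrow(r)) sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s%s",
    r$qname, r$flag,
    ifelse(is.na(r$rname), "*", r$rname),
    ifelse(is.na(r$pos), 0L, r$pos + 1L),  # to 1-based
    r$mapq,
    ifelse(is.na(r$cigar), "*", r$cigar),
    r$seq, r$qual, opt) else character()
  writeLines(c(header_lines(x$header), body), path)
  invisible(path)
}

#' Write a `sam_set` as BAM, optionally coordinate-sorted and indexed
#'
#' @param x a [sam_set()].
#' @param path output `.bam` path.
#' @param sort coordinate-sort the output.
#' @param index write a `.bai` index (requires `sort`).
#' @return the BAM path, invisibly.
#' @export
write_bam <- function(x, path, sort = TRUE, index = sort) {
  stopifnot(grepl("\\.bam$", path))
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  write_sam(x, sam)
  stub <- sub("\\.bam$", "", path)
  if (sort) {
    tmp <- suppressMessages(Rsamtools::asBam(sam, destination = tempfile(),
                                             indexDestination = FALSE, overwrite = TRUE))
    Rsamtools::sortBam(tmp, destination = stub)
    unlink(tmp)
    if (index) Rsamtools::indexBam(path)
  } else {
    suppressMessages(Rsamtools::asBam(sam, destination = stub,
                                      indexDestination = FALSE, overwrite = TRUE))
  }
  invisible(path)
}
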