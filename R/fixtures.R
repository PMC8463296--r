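# Synthetic fixtures: seeded references, SV-implanted haplotypes,
# error-bearing simulated long reads, and SAM files with prescribed edit
# distances. These stand in, at desk scale, for a full SV-simulation stack
# (genome download + SURVIVOR-style implanting + trained read simulator):
# they exercise the pipeline's mechanics exactly, not mapper accuracy.

#' Generate a seeded single-contig reference
#'
#' @param length contig length in bases (>= 1000).
#' @param gc target GC fraction; bases are drawn i.i.d. with
#'   P(G) = P(C) = gc/2.
#' @param seed RNG seed; the same seed reproduces the sequence exactly.
#' @param name contig name.
#' @param path if given, also write the sequence as 60-column-wrapped FASTA.
#' @return a named character vector of length 1 (the sequence), invisibly
#'   carrying the path written (attribute `path`) if any.
#' @export
make_reference <- function(length, gc = 0.4, seed = 1, name = "synth_contig",
                           path = NULL) {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  seqc <- with_seed(seed, paste(
    sample(c("A", "T", "G", "C"), length, replace = TRUE,
           prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
    collapse = ""))
  out <- stats::setNames(seqc, name)
  if (!is.null(path)) {
    ss <- Biostrings::DNAStringSet(out)
    Biostrings::writeXStringSet(ss, path, width = 60)
    attr(out, "path") <- path
  }
  out
}

#' Describe one structural variant to implant
#'
#' All coordinates are 0-based offsets on the original reference. Lengths
#' are >= 50 bases, the conventional lower bound for a structural variant.
#'
#' @param kind `"DEL"`, `"INS"`, `"INV"`, `"DUP"` or `"TRA"`.
#' @param position 0-based start of the affected interval.
#' @param length affected length in bases (INS: payload length).
#' @param payload inserted sequence (INS only; generated if omitted).
#' @param partner_position second block start (TRA only; the two
#'   equal-length blocks are swapped).
#' @export
sv_spec <- function(kind = c("DEL", "INS", "INV", "DUP", "TRA"),
                    position, length, payload = NULL, partner_position = NULL) {
  kind <- match.arg(kind)
  stopifnot(length >= 50, position >= 0)
  if (kind == "INS") {
    if (is.null(payload))
      payload <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                       collapse = "")
    stopifnot(nchar(payload) == length)
  }
  if (kind == "TRA") stopifnot(!is.null(partner_position))
  structure(list(kind = kind, position = as.integer(position),
                 length = as.integer(length), payload = payload,
                 partner_position = if (is.null(partner_position)) NULL
                                    else as.integer(partner_position)),
            class = "sv_spec")
}

sv_interval <- function(sv) {
  # reference footprint: [pos, pos+len) except INS which is a point
  if (sv$kind == "INS") c(sv$position, sv$position)
  else c(sv$position, sv$position + sv$length)
}

#' Implant structural variants into a reference sequence
#'
#' DEL removes `[pos, pos+len)`; INS inserts the payload at `pos`; INV
#' reverse-complements the interval in place; DUP inserts a tandem copy
#' after the interval; TRA swaps two equal-length blocks. Implants are
#' applied right-to-left so earlier coordinates stay valid; reference
#' footprints must not overlap.
#'
#' @param reference a sequence as from [make_reference()] (named character
#'   of length 1) or a path to a FASTA file.
#' @param svs list of [sv_spec()]s.
#' @param alt_path optional FASTA output path for the alternate haplotype.
#' @param truth_path optional BED-like TSV output path for the truth records.
#' @param vcf_path optional minimal VCF 4.2 output path for the truth set.
#' @return list with `alt` (named character sequence) and `truth`
#'   (data.frame: `contig`, `kind`, `start`, `end`, `length` — 0-based
#'   half-open on the original reference).
#' @export
implant_svs <- function(reference, svs, alt_path = NULL, truth_path = NULL,
                        vcf_path = NULL) {
  if (length(reference) == 1 && is.null(names(reference)) && file.exists(reference[1])) {
    ss <- Biostrings::readDNAStringSet(reference)
    reference <- stats::setNames(as.character(ss[1]), sub("\\s.*$", "", names(ss)[1]))
  }
  contig <- names(reference)
  seqc <- unname(reference)
  L <- nchar(seqc)
  ivs <- t(vapply(svs, sv_interval, numeric(2)))
  for (sv in svs) {
    end <- if (sv$kind == "TRA") sv$partner_position + sv$length
           else sv$position + sv$length
    if (sv$position < 0 || end > L)
      dm_stop(sprintf("%s at %d exceeds reference bounds", sv$kind, sv$position),
              "out_of_bounds")
  }
  # overlap check over reference footprints (TRA contributes both blocks)
  spans <- do.call(rbind, lapply(svs, function(sv) {
    if (sv$kind == "TRA")
      rbind(c(sv$position, sv$position + sv$length),
            c(sv$partner_position, sv$partner_position + sv$length))
    else matrix(sv_interval(sv), nrow = 1)
  }))
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  if (nrow(spans) > 1 && any(spans[-1, 1] < spans[-nrow(spans), 2]))
    dm_stop("implant intervals overlap", "overlap_error")

  ord <- order(ivs[, 1], decreasing = TRUE)
  for (sv in svs[ord]) {
    p <- sv$position; len <- sv$length
    seqc <- switch(sv$kind,
      DEL = paste0(substr(seqc, 1, p), substr(seqc, p + len + 1, nchar(seqc))),
      INS = paste0(substr(seqc, 1, p), sv$payload,
                   substr(seqc, p + 1, nchar(seqc))),
      INV = paste0(substr(seqc, 1, p),
                   revcomp_chr(substr(seqc, p + 1, p + len)),
                   substr(seqc, p + len + 1, nchar(seqc))),
      DUP = paste0(substr(seqc, 1, p + len),
                   substr(seqc, p + 1, p + len),
                   substr(seqc, p + len + 1, nchar(seqc))),
      TRA = {
        a <- sv$position; b <- sv$partner_position
        if (a > b) { tmp <- a; a <- b; b <- tmp }
        blk_a <- substr(seqc, a + 1, a + len)
        blk_b <- substr(seqc, b + 1, b + len)
        paste0(substr(seqc, 1, a), blk_b,
               substr(seqc, a + len + 1, b),
               blk_a, substr(seqc, b + len + 1, nchar(seqc)))
      })
  }
  truth <- do.call(rbind, lapply(svs, function(sv) {
    iv <- sv_interval(sv)
    data.frame(contig = contig, kind = sv$kind, start = iv[1],
               end = if (sv$kind == "INS") iv[1] + 1L else iv[2],
               length = sv$length, stringsAsFactors = FALSE)
  }))
  truth <- truth[order(truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  alt <- stats::setNames(seqc, paste0(contig, "_alt"))
  if (!is.null(alt_path))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(alt), alt_path, width = 60)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(vcf_path)) write_truth_vcf(truth, reference, vcf_path)
  list(alt = alt, truth = truth)
}

# minimal VCF 4.2 with symbolic ALT alleles for the SV truth set
write_truth_vcf <- function(truth, reference, path) {
  contig <- names(reference)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig, nchar(reference)),
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           "##ALT=<ID=INV,Description=\"Inversion\">",
           "##ALT=<ID=DUP,Description=\"Duplication\">",
           "##ALT=<ID=TRA,Description=\"Translocation\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ref_base <- substr(rep(unname(reference), nrow(truth)),
                     truth$start + 1L, truth$start + 1L)
  svlen <- ifelse(truth$kind == "DEL", -truth$length, truth$length)
  body <- sprintf("%s\t%d\tsv%d\t%s\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d",
                  truth$contig, truth$start + 1L, seq_len(nrow(truth)),
                  ref_base, truth$kind, truth$kind, truth$end, svlen)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate error-bearing long reads from a reference
#'
#' Reads are drawn uniformly along the contig, strand uniform. Errors use a
#' deliberately simple i.i.d. model: each base substitutes with probability
#' `sub_rate` (to a uniformly chosen different base), and before each base
#' an indel event opens with probability `indel_rate`, with geometric length
#' (mean `1 / (1 - indel_geom_p)` per event) and equal odds of insertion vs
#' deletion. The realized per-read edit count (substitutions + inserted +
#' deleted bases) is recorded exactly in the truth table, enabling
#' parameter-recovery checks of the profiler.
#'
#' @param reference named character sequence or FASTA path.
#' @param n number of reads.
#' @param read_len either one number (fixed length) or `list(mean=, sd=)`
#'   for a truncated-normal length distribution (minimum 200 bp).
#' @param sub_rate per-base substitution probability, in `[0, 0.5)`.
#' @param indel_rate per-position indel-open probability, in `[0, 0.5)`.
#' @param seed RNG seed.
#' @param indel_geom_p geometric continuation probability for indel length.
#' @param fastq_path optional FASTQ output path.
#' @param truth_path optional TSV output path for the truth table.
#' @return list with `reads` (data.frame `name`, `seq`, `qual`) and `truth`
#'   (data.frame `name`, `contig`, `start`, `end`, `strand`, `n_sub`,
#'   `n_ins`, `n_del`, `edits`; `start`/`end` 0-based half-open on the
#'   reference).
#' @export
simulate_reads <- function(reference, n, read_len = 1000, sub_rate = 0.05,
                           indel_rate = 0.05, seed = 1, indel_geom_p = 0.5,
                           fastq_path = NULL, truth_path = NULL) {
  stopifnot(sub_rate >= 0, sub_rate < 0.5, indel_rate >= 0, indel_rate < 0.5)
  if (length(reference) == 1 && is.null(names(reference)) && file.exists(reference[1])) {
    ss <- Biostrings::readDNAStringSet(reference)
    reference <- stats::setNames(as.character(ss[1]), sub("\\s.*$", "", names(ss)[1]))
  }
  contig <- names(reference)
  seqc <- unname(reference)
  L <- nchar(seqc)
  bases <- c("A", "C", "G", "T")
  res <- with_seed(seed, {
    lens <- if (is.numeric(read_len) && length(read_len) == 1)
      rep(as.integer(read_len), n)
    else pmax(200L, as.integer(round(stats::rnorm(n, read_len$mean, read_len$sd))))
    lens <- pmin(lens, L)
    starts <- if (n) vapply(lens, function(l) sample.int(L - l + 1L, 1L) - 1L,
                            integer(1)) else integer()
    strands <- sample(c("+", "-"), n, replace = TRUE)
    reads <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      tmpl <- substr(seqc, starts[i] + 1L, starts[i] + lens[i])
      if (strands[i] == "-") tmpl <- revcomp_chr(tmpl)
      ch <- strsplit(tmpl, "")[[1]]
      m <- length(ch)
      # substitutions
      sub_at <- which(stats::runif(m) < sub_rate)
      for (j in sub_at) ch[j] <- sample(setdiff(bases, ch[j]), 1L)
      n_ins <- 0L; n_del <- 0L
      if (indel_rate > 0) {
        out <- character(0); j <- 1L
        while (j <= length(ch)) {
          if (stats::runif(1) < indel_rate) {
            len <- 1L + stats::rgeom(1, prob = 1 - indel_geom_p)
            if (stats::runif(1) < 0.5) {
              out <- c(out, sample(bases, len, replace = TRUE))
              n_ins <- n_ins + len
            } else {
              ndel <- min(len, length(ch) - j + 1L)
              j <- j + ndel
              n_del <- n_del + ndel
              next
            }
          }
          out <- c(out, ch[j]); j <- j + 1L
        }
        ch <- out
      }
      nm <- paste0("read_", sprintf("%05d", i))
      reads[[i]] <- data.frame(name = nm, seq = paste(ch, collapse = ""),
                               qual = strrep("I", length(ch)),
                               stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(name = nm, contig = contig, start = starts[i],
                               end = starts[i] + lens[i], strand = strands[i],
                               n_sub = length(sub_at), n_ins = n_ins,
                               n_del = n_del,
                               edits = length(sub_at) + n_ins + n_del,
                               stringsAsFactors = FALSE)
    }
    list(reads = do.call(rbind, reads) %||% data.frame(
           name = character(), seq = character(), qual = character()),
         truth = do.call(rbind, truth) %||% data.frame())
  })
  if (!is.null(fastq_path)) write_fastq(res$reads, fastq_path)
  if (!is.null(truth_path))
    utils::write.table(res$truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  res
}

#' Write a SAM file with prescribed records
#'
#' The fixture route for exact, seed-free tests: every record carries
#' exactly the flags, CIGAR and NM the manifest prescribes, so
#' [build_profile()] on the file recovers exactly the prescribed E values.
#'
#' @param manifest data.frame, one row per record: `read_name`, `flag`,
#'   `rname`, `pos` (0-based), `cigar`, `nm`; optional `mapq`, `seq`,
#'   `qual`, `md`. When `seq` is omitted a random sequence of the CIGAR's
#'   query width is generated (seeded by `seed`).
#' @param ref_lengths named integer vector of reference lengths; computed
#'   from the records' rightmost spans when omitted.
#' @param path output SAM path.
#' @param seed seed for generated sequences.
#' @return the path, invisibly.
#' @export
make_sam_fixture <- function(manifest, path, ref_lengths = NULL, seed = 1) {
  need <- c("read_name", "flag", "rname", "pos", "cigar", "nm")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    dm_stop(paste("manifest missing columns:", paste(miss, collapse = ", ")),
            "inconsistent_manifest")
  m <- manifest
  unmapped <- bitwAnd(as.integer(m$flag), FLAG_UNMAPPED) != 0L
  qw <- rep(0L, nrow(m))
  qw[!unmapped] <- cigar_query_width(m$cigar[!unmapped])
  if (!"seq" %in% names(m)) {
    m$seq <- with_seed(seed, vapply(pmax(qw, 1L), function(w)
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = ""), ""))
  }
  if (!"qual" %in% names(m)) m$qual <- strrep("I", nchar(m$seq))
  bad <- !unmapped & nchar(m$seq) != qw & m$seq != "*"
  if (any(bad))
    dm_stop(sprintf("CIGAR/sequence length mismatch for: %s",
                    paste(m$read_name[bad], collapse = ", ")),
            "inconsistent_manifest")
  if (is.null(ref_lengths)) {
    mm <- m[!unmapped, , drop = FALSE]
    span <- mm$pos + GenomicAlignments::cigarWidthAlongReferenceSpace(mm$cigar)
    ref_lengths <- tapply(span, mm$rname, max)
  }
  rec <- data.frame(
    qname = m$read_name, flag = as.integer(m$flag),
    rname = ifelse(unmapped, NA_character_, m$rname),
    pos = ifelse(unmapped, NA_integer_, as.integer(m$pos)),
    mapq = if ("mapq" %in% names(m)) as.integer(m$mapq) else 60L,
    cigar = ifelse(unmapped, NA_character_, m$cigar),
    seq = m$seq, qual = m$qual,
    nm = ifelse(unmapped, NA_integer_, as.integer(m$nm)),
    md = if ("md" %in% names(m)) m$md else NA_character_,
    stringsAsFactors = FALSE)
  hdr <- sam_header(data.frame(name = names(ref_lengths),
                               length = as.integer(ref_lengths)))
  write_sam(sam_set(rec, hdr), path)
  invisible(path)
}
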