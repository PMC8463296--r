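#' Describe a mapper backend
#'
#' A uniform contract for the two mapping stages: a fast minimap2-style
#' mapper for the first pass and a sensitive NGMLR-style mapper for
#' realignment, plus a deterministic, manifest-driven mock backend so the
#' entire pipeline can be exercised without external binaries.
#'
#' @param kind `"minimap2"`, `"ngmlr"` or `"mock"`.
#' @param executable path to the binary (ignored by the mock).
#' @param preset sequencing platform: `"ont"`, `"pacbio_clr"` or
#'   `"pacbio_hifi"`; selects the backend's documented preset arguments.
#' @param extra_args character vector appended verbatim after the preset.
#' @param threads worker threads (>= 1).
#' @param manifest mock only: data.frame scripting the mock's output, one
#'   row per read with columns `read_name`, `rname`, `pos` (0-based),
#'   `cigar`, `nm`, `flag`, and optionally `mapq`. Reads absent from the
#'   manifest are emitted as unmapped records.
#' @return a `mapper_spec`.
#' @export
mapper_spec <- function(kind = c("minimap2", "ngmlr", "mock"),
                        executable = kind, preset = c("ont", "pacbio_clr", "pacbio_hifi"),
                        extra_args = character(), threads = 1L, manifest = NULL) {
  kind <- match.arg(kind)
  preset <- match.arg(preset)
  stopifnot(threads >= 1)
  structure(list(kind = kind, name = kind, executable = executable,
                 preset = preset, extra_args = extra_args,
                 threads = as.integer(threads), manifest = manifest),
            class = c(paste0(kind, "_spec"), "mapper_spec"))
}

#' @export
print.mapper_spec <- function(x, ...) {
  cat(sprintf("<mapper_spec> %s (%s preset), %d thread(s)\n",
              x$kind, x$preset, x$threads))
  invisible(x)
}

#' Preset argument list for a backend
#'
#' minimap2 uses its long-read `-ax` presets (`map-ont`, `map-pb`,
#' `map-hifi`); NGMLR distinguishes only `-x ont` and `-x pacbio`. The mock
#' ignores presets. `extra_args` are appended last so they can override.
#'
#' @param spec a [mapper_spec()].
#' @return character vector of command-line arguments.
#' @export
preset_args <- function(spec) UseMethod("preset_args")

#' @export
preset_args.minimap2_spec <- function(spec) {
  px <- switch(spec$preset,
               ont = "map-ont", pacbio_clr = "map-pb", pacbio_hifi = "map-hifi",
               dm_stop(paste("unsupported preset:", spec$preset), "unsupported_preset"))
  c("-ax", px, "--MD", "-t", spec$threads, spec$extra_args)
}

#' @export
preset_args.ngmlr_spec <- function(spec) {
  px <- switch(spec$preset,
               ont = "ont", pacbio_clr = "pacbio", pacbio_hifi = "pacbio",
               dm_stop(paste("unsupported preset:", spec$preset), "unsupported_preset"))
  c("-x", px, "-t", spec$threads, spec$extra_args)
}

#' @export
preset_args.mock_spec <- function(spec) character()

backend_version <- function(spec) {
  if (spec$kind == "mock") return("mock-1.0")
  out <- tryCatch(
    suppressWarnings(system2(spec$executable, "--version",
                             stdout = TRUE, stderr = TRUE)),
    error = function(e) NA_character_)
  if (length(out)) trimws(out[1]) else NA_character_
}

#' Run a mapper backend on a FASTQ against a reference
#'
#' Invokes the backend, converts its SAM output to BAM, and validates that
#' mapped records carry an edit distance (NM directly, or MD from which NM
#' is reconstructible). The output read-name set is a subset of the input
#' FASTQ's names; reads the mapper could not place appear as unmapped
#' records.
#'
#' @param spec a [mapper_spec()].
#' @param reads FASTQ path.
#' @param reference FASTA path.
#' @param out_bam output BAM path (unsorted; sorting happens once, at merge).
#' @return a `mapper_result`: list with `alignment_path`, `n_input_reads`,
#'   `n_records`, `elapsed` (seconds), `version`, `command`.
#' @export
run_mapper <- function(spec, reads, reference, out_bam = tempfile(fileext = ".bam")) {
  stopifnot(inherits(spec, "mapper_spec"))
  if (!file.exists(reads)) dm_stop(paste("reads not found:", reads), "io")
  if (!file.exists(reference)) dm_stop(paste("reference not found:", reference), "io")
  t0 <- proc.time()[["elapsed"]]
  fq <- read_fastq(reads)
  res <- if (spec$kind == "mock") run_mock(spec, fq, reference, out_bam)
         else run_subprocess(spec, reads, reference, out_bam)
  validate_mapper_output(res$set, fq$name)
  structure(list(alignment_path = out_bam,
                 n_input_reads = nrow(fq),
                 n_records = nrow(res$set$records),
                 elapsed = proc.time()[["elapsed"]] - t0,
                 version = backend_version(spec),
                 command = res$command),
            class = "mapper_result")
}

reference_dict <- function(reference) {
  ref <- Biostrings::readDNAStringSet(reference)
  data.frame(name = sub("\\s.*$", "", names(ref)),
             length = Biostrings::width(ref), stringsAsFactors = FALSE)
}

# deterministic script-driven backend: the manifest decides each read's fate
run_mock <- function(spec, fq, reference, out_bam) {
  man <- spec$manifest
  if (is.null(man)) man <- data.frame(read_name = character(), rname = character(),
                                      pos = integer(), cigar = character(),
                                      nm = integer(), flag = integer())
  sq <- reference_dict(reference)
  hdr <- sam_header(sq)
  hdr <- append_pg(hdr, "mock", "mock-mapper", "mock")
  n <- nrow(fq)
  idx <- match(fq$name, man$read_name)
  hit <- !is.na(idx)
  m <- man[idx[hit], , drop = FALSE]
  flag <- as.integer(m$flag)
  is_rev <- bitwAnd(flag, FLAG_REVERSE) != 0L
  seqs <- fq$seq[hit]; quals <- fq$qual[hit]
  if (any(is_rev)) {  # SAM stores reverse-strand alignments revcomped
    seqs[is_rev] <- revcomp_chr(seqs[is_rev])
    quals[is_rev] <- rev_chr(quals[is_rev])
  }
  mapped <- data.frame(
    qname = fq$name[hit], flag = flag, rname = m$rname, pos = as.integer(m$pos),
    mapq = if ("mapq" %in% names(m)) as.integer(m$mapq) else rep(60L, nrow(m)),
    cigar = m$cigar, seq = seqs, qual = quals,
    nm = as.integer(m$nm), md = rep(NA_character_, nrow(m)),
    stringsAsFactors = FALSE)
  n_un <- sum(!hit)
  unmapped <- data.frame(
    qname = fq$name[!hit], flag = rep(FLAG_UNMAPPED, n_un),
    rname = rep(NA_character_, n_un), pos = rep(NA_integer_, n_un),
    mapq = rep(0L, n_un), cigar = rep(NA_character_, n_un),
    seq = fq$seq[!hit], qual = fq$qual[!hit],
    nm = rep(NA_integer_, n_un), md = rep(NA_character_, n_un),
    stringsAsFactors = FALSE)
  set <- sam_set(rbind(mapped, unmapped), hdr)
  bad <- cigar_query_width(set$records$cigar[!is.na(set$records$cigar)]) !=
    nchar(set$records$seq[!is.na(set$records$cigar)])
  if (any(bad))
    dm_stop("mock manifest CIGAR does not consume the read length", "inconsistent_manifest")
  write_bam(set, out_bam, sort = FALSE, index = FALSE)
  list(set = set, command = "mock")
}

run_subprocess <- function(spec, reads, reference, out_bam) {
  if (!nzchar(Sys.which(spec$executable)))
    dm_stop(paste("mapper executable not found:", spec$executable), "backend_failure")
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  args <- switch(spec$kind,
    minimap2 = c(preset_args(spec), reference, reads),
    ngmlr = c(preset_args(spec), "-r", reference, "-q", reads))
  err <- tempfile()
  status <- suppressWarnings(system2(spec$executable, args, stdout = sam, stderr = err))
  if (status != 0)
    dm_stop(sprintf("%s exited with status %d: %s", spec$kind, status,
                    paste(readLines(err, warn = FALSE), collapse = "; ")),
            "backend_failure")
  cmd <- paste(c(spec$executable, args), collapse = " ")
  if (file.size(sam) == 0 || !any(!startsWith(readLines(sam, warn = FALSE), "@"))) {
    # header-only or empty output (e.g. empty FASTQ): emit an empty BAM
    set <- sam_set(empty_records(), sam_header(reference_dict(reference)))
    write_bam(set, out_bam, sort = FALSE, index = FALSE)
    return(list(set = set, command = cmd))
  }
  set <- read_alignments(sam)
  write_bam(set, out_bam, sort = FALSE, index = FALSE)
  list(set = set, command = cmd)
}

empty_records <- function() {
  data.frame(qname = character(), flag = integer(), rname = character(),
             pos = integer(), mapq = integer(), cigar = character(),
             seq = character(), qual = character(), nm = integer(),
             md = character(), stringsAsFactors = FALSE)
}

validate_mapper_output <- function(set, input_names) {
  rec <- set$records
  if (nrow(rec) && !all(rec$qname %in% input_names))
    dm_stop("mapper emitted records for reads not in its input", "backend_failure")
  cl <- classify_alignment(rec$flag)
  mapped <- rec[cl != "unmapped", , drop = FALSE]
  if (nrow(mapped) && all(is.na(mapped$nm)) && all(is.na(mapped$md)))
    dm_stop("mapper output carries neither NM nor MD on any mapped record",
            "missing_nm")
  invisible(TRUE)
}
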