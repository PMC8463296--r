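# Shared fixture builders for the suite.

# one-row-per-record manifest with sensible defaults
rec_manifest <- function(read_name, flag = 0L, rname = "chr_s", pos = 0L,
                         cigar = "100M", nm = 0L, ...) {
  data.frame(read_name = read_name, flag = flag, rname = rname, pos = pos,
             cigar = cigar, nm = nm, ..., stringsAsFactors = FALSE)
}

# fixture SAM on disk -> sam_set
fixture_set <- function(manifest, ref_lengths = c(chr_s = 100000L)) {
  path <- tempfile(fileext = ".sam")
  make_sam_fixture(manifest, path, ref_lengths = ref_lengths)
  read_alignments(path)
}

# a complete mock-backed pipeline setup: n reads simulated without error,
# mapper A scripted from the truth with prescribed per-read NM, mapper B
# scripted with nm_b for every read.
mock_pipeline_setup <- function(n = 100, nm_a = NULL, nm_b = 1L, seed = 11,
                                percentile = 90, read_len = 400, ...) {
  dir <- tempfile("mockpipe_")
  dir.create(dir)
  ref <- make_reference(20000, 0.45, seed = seed,
                        path = file.path(dir, "ref.fa"))
  sim <- simulate_reads(ref, n = n, read_len = read_len, sub_rate = 0,
                        indel_rate = 0, seed = seed + 1)
  fq <- file.path(dir, "reads.fastq")
  write_fastq(sim$reads, fq)
  tr <- sim$truth
  if (is.null(nm_a)) nm_a <- seq_len(n)  # distinct E values by construction
  manA <- data.frame(read_name = tr$name, rname = tr$contig, pos = tr$start,
                     cigar = paste0(tr$end - tr$start, "M"), nm = nm_a,
                     flag = ifelse(tr$strand == "-", 16L, 0L))
  manB <- manA
  manB$nm <- nm_b
  cfg <- pipeline_config(
    reads = fq, reference = attr(ref, "path"), percentile = percentile,
    backend_fast = mapper_spec("mock", manifest = manA),
    backend_sensitive = mapper_spec("mock", manifest = manB),
    workdir = file.path(dir, "work"), keep_intermediates = TRUE, ...)
  list(cfg = cfg, truth = tr, manA = manA, manB = manB, dir = dir,
       ref = ref, fastq = fq)
}
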