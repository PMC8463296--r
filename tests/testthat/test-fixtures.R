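test_that("reference generation is seed-deterministic with the stated composition", {
  a <- make_reference(10000, 0.5, seed = 42)
  b <- make_reference(10000, 0.5, seed = 42)
  expect_identical(unname(a), unname(b))
  expect_false(identical(unname(a), unname(make_reference(10000, 0.5, seed = 43))))
  # degenerate composition
  gc1 <- make_reference(10000, 1.0, seed = 7)
  expect_true(grepl("^[GC]+$", unname(gc1)))
  # GC count within the binomial 99% interval around 0.4 * 10000
  gc4 <- make_reference(10000, 0.4, seed = 7)
  n_gc <- nchar(gsub("[AT]", "", unname(gc4)))
  bounds <- stats::qbinom(c(0.005, 0.995), 10000, 0.4)
  expect_gte(n_gc, bounds[1])
  expect_lte(n_gc, bounds[2])
  # FASTA writing wraps at 60 columns and round-trips
  fa <- tempfile(fileext = ".fa")
  make_reference(1234, 0.5, seed = 1, path = fa)
  lines <- readLines(fa)
  expect_true(all(nchar(lines[-1]) <= 60))
  back <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(back[[1]]), unname(make_reference(1234, 0.5, seed = 1)))
})

test_that("SV implanting follows each type's length arithmetic", {
  ref <- make_reference(10000, 0.5, seed = 10)
  del <- implant_svs(ref, list(sv_spec("DEL", 2000, 100)))
  expect_equal(unname(nchar(del$alt)), 9900)
  ins <- implant_svs(ref, list(sv_spec("INS", 2000, 80,
                                       payload = strrep("ACGT", 20))))
  expect_equal(unname(nchar(ins$alt)), 10080)
  expect_equal(substr(unname(ins$alt), 2001, 2080), strrep("ACGT", 20))
  dup <- implant_svs(ref, list(sv_spec("DUP", 3000, 60)))
  expect_equal(unname(nchar(dup$alt)), 10060)
  unit <- substr(unname(ref), 3001, 3060)
  expect_equal(substr(unname(dup$alt), 3001, 3120), paste0(unit, unit))
  # INV is an involution
  inv1 <- implant_svs(ref, list(sv_spec("INV", 4000, 200)))
  inv2 <- implant_svs(inv1$alt, list(sv_spec("INV", 4000, 200)))
  expect_equal(unname(inv2$alt), unname(ref))
  # TRA swaps two equal-length blocks
  tra <- implant_svs(ref, list(sv_spec("TRA", 1000, 100, partner_position = 8000)))
  expect_equal(unname(nchar(tra$alt)), 10000)
  expect_equal(substr(unname(tra$alt), 1001, 1100), substr(unname(ref), 8001, 8100))
  expect_equal(substr(unname(tra$alt), 8001, 8100), substr(unname(ref), 1001, 1100))
})

test_that("SV implanting validates intervals", {
  ref <- make_reference(5000, 0.5, seed = 10)
  expect_error(implant_svs(ref, list(sv_spec("DEL", 100, 100),
                                     sv_spec("INV", 150, 100))),
               class = "dualmap_overlap_error")
  expect_error(implant_svs(ref, list(sv_spec("DEL", 4990, 100))),
               class = "dualmap_out_of_bounds")
  expect_error(sv_spec("DEL", 100, 30))  # below the 50 bp SV floor
})

test_that("SV truth exports as BED-like TSV and VCF", {
  ref <- make_reference(10000, 0.5, seed = 10)
  tsv <- tempfile(fileext = ".tsv"); vcf <- tempfile(fileext = ".vcf")
  r <- implant_svs(ref, list(sv_spec("DEL", 2000, 100),
                             sv_spec("DUP", 6000, 60)),
                   truth_path = tsv, vcf_path = vcf)
  truth <- utils::read.delim(tsv)
  expect_equal(truth$kind, c("DEL", "DUP"))
  expect_equal(truth$start, c(2000, 6000))      # 0-based half-open
  expect_equal(truth$end, c(2100, 6060))
  v <- readLines(vcf)
  expect_equal(v[1], "##fileformat=VCFv4.2")
  body <- v[!startsWith(v, "#")]
  expect_length(body, 2)
  expect_true(grepl("SVTYPE=DEL;END=2100;SVLEN=-100", body[1]))
  expect_true(grepl("\t2001\t", body[1], fixed = TRUE))  # VCF is 1-based
})

test_that("zero-error reads are exact substrings of the reference", {
  ref <- make_reference(20000, 0.45, seed = 20)
  sim <- simulate_reads(ref, 30, read_len = 500, sub_rate = 0,
                        indel_rate = 0, seed = 21)
  expect_equal(sim$truth$edits, rep(0L, 30))
  for (i in seq_len(30)) {
    tmpl <- substr(unname(ref), sim$truth$start[i] + 1, sim$truth$end[i])
    if (sim$truth$strand[i] == "-") tmpl <- rc_chr(tmpl)
    expect_identical(sim$reads$seq[i], tmpl)
  }
  # vacuous input
  none <- simulate_reads(ref, 0, seed = 1)
  expect_equal(nrow(none$reads), 0)
})

test_that("simulated edit counts are self-consistent and near binomial moments", {
  ref <- make_reference(50000, 0.45, seed = 30)
  sim <- simulate_reads(ref, 300, read_len = 1000, sub_rate = 0.1,
                        indel_rate = 0, seed = 31)
  expect_equal(sim$truth$edits, sim$truth$n_sub)
  # realized substitutions equal direct base-by-base comparison with template
  i <- which.max(sim$truth$edits)
  tmpl <- substr(unname(ref), sim$truth$start[i] + 1, sim$truth$end[i])
  if (sim$truth$strand[i] == "-") tmpl <- rc_chr(tmpl)
  diffs <- sum(strsplit(tmpl, "")[[1]] != strsplit(sim$reads$seq[i], "")[[1]])
  expect_equal(diffs, sim$truth$edits[i])
  # mean edits/read within 3 sigma of Binomial(1000, 0.1) for the mean of 300
  mu <- 1000 * 0.1
  se3 <- 3 * sqrt(1000 * 0.1 * 0.9 / 300)
  expect_lt(abs(mean(sim$truth$edits) - mu), se3)
  # indels contribute their full lengths
  sim2 <- simulate_reads(ref, 50, read_len = 500, sub_rate = 0,
                         indel_rate = 0.02, seed = 32)
  expect_equal(sim2$truth$edits, sim2$truth$n_ins + sim2$truth$n_del)
  expect_equal(nchar(sim2$reads$seq),
               500L - sim2$truth$n_del + sim2$truth$n_ins)
})

test_that("read simulation is byte-identical under a fixed seed", {
  ref <- make_reference(20000, 0.45, seed = 20)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulate_reads(ref, 20, read_len = 400, sub_rate = 0.05, indel_rate = 0.01,
                 seed = 77, fastq_path = f1)
  simulate_reads(ref, 20, read_len = 400, sub_rate = 0.05, indel_rate = 0.01,
                 seed = 77, fastq_path = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("SAM fixtures realize prescribed E values exactly", {
  man <- rec_manifest(sprintf("q%03d", 1:100), nm = 1:100)
  prof <- build_profile(fixture_set(man), "fixture")
  expect_setequal(prof$E, (1:100) / 100)
  # adding one secondary per read leaves the profile size unchanged
  man2 <- rbind(man, rec_manifest(sprintf("q%03d", 1:100), flag = 256L, nm = 0L))
  prof2 <- build_profile(fixture_set(man2), "fixture")
  expect_equal(nrow(prof2), 100)
  expect_setequal(prof2$E, (1:100) / 100)
  # duplicate primary in a manifest surfaces downstream
  dup <- rbind(man[1, ], man[1, ])
  expect_error(build_profile(fixture_set(dup), "fixture"),
               class = "dualmap_duplicate_primary")
  # missing manifest columns are rejected up front
  expect_error(make_sam_fixture(data.frame(read_name = "a"), tempfile()),
               class = "dualmap_inconsistent_manifest")
})
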