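test_that("normalized edit distance is e over aligned length", {
  rec <- data.frame(nm = c(0L, 5L, 7L), md = NA_character_,
                    cigar = c("100M", "50M", "10S80M5I5D"))
  expect_equal(normalized_edit_distance(rec), c(0, 0.1, 7 / 85))
  # read-length denominator includes the soft clip
  expect_equal(normalized_edit_distance(rec, denominator = "read")[3], 7 / 95)
})

test_that("profiles keep one entry per read, from the primary record only", {
  man <- rbind(
    rec_manifest("r1", flag = 0L,    cigar = "20M", nm = 2L),
    rec_manifest("r1", flag = 256L,  cigar = "20M", nm = 9L),
    rec_manifest("r1", flag = 2048L, cigar = "10M", nm = 5L),
    rec_manifest("r2", flag = 0L,    cigar = "40M", nm = 4L))
  prof <- build_profile(fixture_set(man), "t")
  expect_equal(nrow(prof), 2)
  expect_equal(prof$E[prof$read_name == "r1"], 0.1)  # 2/20, secondary ignored
  expect_equal(prof$E[prof$read_name == "r2"], 0.1)
})

test_that("unmapped-only streams give an empty profile; duplicates raise", {
  unm <- fixture_set(rec_manifest(c("u1", "u2"), flag = 4L, nm = 0L))
  prof <- build_profile(unm, "t")
  expect_equal(nrow(prof), 0)
  expect_equal(attr(prof, "n_unmapped"), 2L)
  dup <- fixture_set(rec_manifest(c("x", "x"), flag = 0L, nm = 0L))
  expect_error(build_profile(dup, "t"), class = "dualmap_duplicate_primary")
})

test_that("profile round-trips prescribed edit distances exactly", {
  nm_i <- sample(0:100, 100, replace = TRUE)
  man <- rec_manifest(sprintf("r%03d", 1:100), nm = nm_i)
  prof <- build_profile(fixture_set(man), "t")
  expect_equal(prof$E[match(man$read_name, prof$read_name)], nm_i / 100)
})

test_that("nearest-rank percentile matches its stated examples", {
  prof100 <- structure(data.frame(read_name = sprintf("r%d", 1:100),
                                  E = (1:100) / 100),
                       class = c("ed_profile", "data.frame"))
  expect_equal(percentile_threshold(prof100, 90), 0.90)
  expect_equal(percentile_threshold(prof100, 100), max(prof100$E))
  expect_identical(percentile_threshold(prof100, 0), SENTINEL_BELOW_MIN)
  one <- structure(data.frame(read_name = "a", E = 0.3),
                   class = c("ed_profile", "data.frame"))
  expect_equal(percentile_threshold(one, 50), 0.3)
  empty <- structure(data.frame(read_name = character(), E = numeric()),
                     class = c("ed_profile", "data.frame"))
  expect_error(percentile_threshold(empty, 90), class = "dualmap_empty_profile")
})

test_that("percentile agrees with a brute-force sort-and-index oracle", {
  set.seed(501)
  for (n in c(1:20, sample(21:200, 15))) {
    E <- round(stats::runif(n), 3)  # rounded to force ties
    prof <- structure(data.frame(read_name = as.character(seq_len(n)), E = E),
                      class = c("ed_profile", "data.frame"))
    for (p in 0:100)
      expect_identical(percentile_threshold(prof, p), oracle_percentile(E, p))
  }
})

test_that("flagged fraction is bounded by (100 - p)/100, monotone in p", {
  set.seed(502)
  for (i in 1:25) {
    n <- sample(1:300, 1)
    E <- sample(round(stats::runif(n), sample(1:4, 1)))
    prof <- structure(data.frame(read_name = as.character(seq_len(n)), E = E),
                      class = c("ed_profile", "data.frame"))
    prev_flagged <- Inf
    for (p in c(0, 10, 25, 50, 75, 90, 100)) {
      thr <- percentile_threshold(prof, p)
      flagged <- sum(E > thr)
      if (p > 0) expect_lte(flagged / n, (100 - p) / 100)
      expect_lte(flagged, prev_flagged)
      prev_flagged <- flagged
    }
    # equality when E distinct and p*n/100 integral
    if (!anyDuplicated(E)) {
      for (p in c(10, 50, 90)) {
        if ((p * n) %% 100 == 0)
          expect_equal(sum(E > percentile_threshold(prof, p)),
                       n * (100 - p) / 100)
      }
    }
  }
})

test_that("distribution summaries: interpolated quartiles and conserving histogram", {
  prof <- structure(data.frame(read_name = c("a", "b", "c"), E = c(0.1, 0.2, 0.3)),
                    class = c("ed_profile", "data.frame"))
  s <- summarize_profile(prof, bins = 4)
  expect_equal(s$median_E, 0.2)
  expect_equal(s$q1, 0.15)  # linear interpolation
  expect_equal(sum(s$histogram$count), 3)
  # degenerate: all values equal land in a single bin
  deg <- structure(data.frame(read_name = letters[1:5], E = rep(0.05, 5)),
                   class = c("ed_profile", "data.frame"))
  sd5 <- summarize_profile(deg, bins = 4)
  expect_equal(sum(sd5$histogram$count > 0), 1)
  expect_equal(sum(sd5$histogram$count), 5)
  # seeded draw: counts conserve n, bins tile [0, max]
  set.seed(503)
  big <- structure(data.frame(read_name = as.character(1:1000),
                              E = stats::rbeta(1000, 2, 20)),
                   class = c("ed_profile", "data.frame"))
  sb <- summarize_profile(big, bins = 30)
  expect_equal(sum(sb$histogram$count), 1000)
  expect_equal(sb$histogram$bin_left[1], 0)
  expect_equal(sb$histogram$bin_right[30], max(big$E))
  expect_equal(sb$histogram$bin_left[-1], sb$histogram$bin_right[-30])
  expect_error(summarize_profile(structure(
    data.frame(read_name = character(), E = numeric()),
    class = c("ed_profile", "data.frame"))), class = "dualmap_empty_profile")
})

test_that("profile TSV and summary JSON exports round-trip", {
  man <- rec_manifest(c("a", "b"), nm = c(1L, 2L))
  prof <- build_profile(fixture_set(man), "mapperX")
  tsv <- tempfile(fileext = ".tsv")
  write_profile_tsv(prof, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(back$E, prof$E)
  expect_equal(unique(back$source_label), "mapperX")
  js <- tempfile(fileext = ".json")
  write_summary_json(summarize_profile(prof, 5), js)
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$n, 2)
  expect_equal(parsed$source_label, "mapperX")
})
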