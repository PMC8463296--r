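# Independent oracles, deliberately implemented with none of the package's
# own CIGAR/percentile machinery.

# CIGAR walk: total length of the given operations
oracle_cigar_sum <- function(cigar, ops) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(lens[op %in% ops])
}

# nearest-rank percentile by explicit sort-and-index
oracle_percentile <- function(E, p) {
  if (p == 0) return(-Inf)
  sort(E)[ceiling(p * length(E) / 100)]
}

# edit distance from MD + CIGAR by direct token counting
oracle_md_nm <- function(md, cigar) {
  toks <- regmatches(md, gregexpr("[0-9]+|\\^[A-Z]+|[A-Z]", md))[[1]]
  n_mm <- sum(grepl("^[A-Z]$", toks))
  n_mm + oracle_cigar_sum(cigar, "I") + oracle_cigar_sum(cigar, "D")
}

# random CIGAR over aligned/clip ops with at least one aligned op
random_cigar <- function() {
  n_ops <- sample(1:6, 1)
  ops <- sample(c("M", "I", "D", "S", "=", "X"), n_ops, replace = TRUE)
  if (!any(ops %in% c("M", "I", "=", "X"))) ops <- c(ops, "M")
  # S only legal at the ends
  inner <- ops[ops != "S"]
  ops <- c(if (stats::runif(1) < 0.3) "S", inner, if (stats::runif(1) < 0.3) "S")
  lens <- sample(1:200, length(ops), replace = TRUE)
  paste0(lens, ops, collapse = "")
}

rc_chr <- function(s) chartr("ACGT", "TGCA",
                             vapply(strsplit(s, ""), function(x)
                               paste(rev(x), collapse = ""), ""))
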