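#' @keywords internal
"_PACKAGE"

# Signal a classed error so callers can discriminate failure modes
# (missing_evidence, malformed_tag, empty_alignment, duplicate_primary,
# empty_profile, orphan_record, unextractable_read, backend_failure,
# missing_nm, header_mismatch, cross_contamination, unsupported_preset,
# overlap_error, out_of_bounds, inconsistent_manifest).
dm_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("dualmap_", class), "dualmap_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

dm_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("dualmap_", class), "dualmap_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Sentinel threshold lying strictly below every normalized edit distance
#'
#' Returned by [percentile_threshold()] at `p = 0` so that the strict
#' comparison `E > threshold` flags every profiled read.
#' @export
SENTINEL_BELOW_MIN <- -Inf

# run an expression with a private RNG stream, restoring global state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
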