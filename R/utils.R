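#' Run code under a fixed RNG seed, if one is given
#'
#' Determinism helper used by every stochastic operation in the package:
#' when `seed` is `NULL` the current RNG stream is used (and advanced),
#' otherwise the code runs under `withr::with_seed()` so the surrounding
#' RNG state is untouched.
#'
#' @param seed integer scalar or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
#' @noRd
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a 0-based half-open genomic interval data.frame
#' @noRd
validate_intervals <- function(x, require_strand = FALSE) {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end", if (require_strand) "strand")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("interval table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop("invalid interval(s): require 0 <= start < end")
  }
  if (require_strand && !all(x$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  invisible(x)
}

#' Construct a genomic interval table (0-based, half-open)
#'
#' Coordinates follow the BED convention throughout the package: `start` is
#' 0-based inclusive, `end` exclusive.
#'
#' @param chrom chromosome names.
#' @param start,end integer vectors, `0 <= start < end`.
#' @param strand `"+"` or `"-"` (recycled).
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @examples
#' genomic_interval("chr1", 9500, 10000)
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  out <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), length(chrom)),
    stringsAsFactors = FALSE
  )
  validate_intervals(out, require_strand = TRUE)
  out
}
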