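## Sequence encoding: lowercase atcgn strings -> strand-doubled one-hot
## matrices.  Column order is fixed as (null, a, t, c, g) so that
## a = 01000, t = 00100, c = 00010, g = 00001 and any unknown base maps to
## the null code 10000.

ENC_ALPHABET <- c("null", "a", "t", "c", "g")

#' Reverse complement of a lowercase DNA string
#'
#' Alphabet is `{a,t,c,g,n}`; `n` complements to `n`.  Vectorised over
#' `seq`.
#'
#' @param seq character vector of sequences.
#' @return character vector of reverse complements.
#' @examples
#' reverse_complement("aaac")  # "gttt"
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("atcgn", "tagcn", seq)
  vapply(comp, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Strand-double a 100-base window
#'
#' Concatenates the forward window with its reverse complement, yielding the
#' 200-symbol string that the classifier consumes.  Presenting both strands
#' lets one model recognise a motif irrespective of the strand it was
#' planted on.
#'
#' @param seq a single 100-base string over `{a,t,c,g,n}`.
#' @return a 200-character string: `seq` followed by
#'   `reverse_complement(seq)`.
#' @export
double_sequence <- function(seq) {
  stopifnot(length(seq) == 1L)
  if (nchar(seq) != 100L) {
    stop("double_sequence() expects a 100-base window, got ", nchar(seq), " bases")
  }
  paste0(seq, reverse_complement(seq))
}

#' One-hot encode a (doubled) sequence
#'
#' Each symbol becomes a 5-bit row over the columns
#' `(null, a, t, c, g)`; `n` and any unexpected character take the null
#' code `10000`.  Every row sums to exactly 1.
#'
#' @param seq200 a single 200-symbol string (any length is accepted; the
#'   classifier requires 200).
#' @return integer matrix with `nchar(seq200)` rows and 5 columns.
#' @examples
#' one_hot(double_sequence(strrep("acgtn", 20)))
#' @export
one_hot <- function(seq200) {
  stopifnot(length(seq200) == 1L)
  codes <- seq_codes_single(seq200)
  n <- length(codes)
  m <- matrix(0L, nrow = n, ncol = 5L, dimnames = list(NULL, ENC_ALPHABET))
  m[cbind(seq_len(n), codes + 1L)] <- 1L
  m
}

#' Encode a 100-base window as a 200x5 one-hot matrix
#'
#' Convenience composition of [double_sequence()] and [one_hot()].
#'
#' @param seq100 a single 100-base window.
#' @return 200x5 integer matrix.
#' @export
encode_window <- function(seq100) {
  one_hot(double_sequence(seq100))
}

## integer codes 0..4 over (null,a,t,c,g); unknowns -> 0
seq_codes_single <- function(s) {
  lut <- rep(0L, 256L)
  lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("t")] <- 2L
  lut[utf8ToInt("c")] <- 3L
  lut[utf8ToInt("g")] <- 4L
  lut[utf8ToInt(s) + 0L]
}

#' Integer-code a batch of 100-base windows for the classifier
#'
#' Compact representation used on the training path: each window is doubled
#' (forward + reverse complement) and each of the 200 symbols is coded
#' 0=null, 1=a, 2=t, 3=c, 4=g.  One-hot expansion happens batch-wise inside
#' the model, so the full corpus is never materialised as matrices.
#' `one_hot(double_sequence(s))` and `encode_codes(s)` describe the same
#' matrix.
#'
#' @param seqs character vector of 100-base windows.
#' @return integer matrix, one row per window, 200 columns.
#' @export
encode_codes <- function(seqs) {
  bad <- nchar(seqs) != 100L
  if (any(bad)) {
    stop(sum(bad), " window(s) are not 100 bases long")
  }
  doubled <- paste0(seqs, reverse_complement(seqs))
  out <- matrix(0L, nrow = length(seqs), ncol = 200L)
  for (i in seq_along(doubled)) {
    out[i, ] <- seq_codes_single(doubled[[i]])
  }
  out
}
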