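## Readers/writers for the standard formats (FASTA, BED-like peak TSV,
## wiggle fixedStep / bedGraph) and promoter construction.  All coordinates
## are 0-based half-open internally; 1-based inputs (wiggle fixedStep) are
## converted on read.

#' Read a FASTA file into a named character vector
#'
#' Sequences are lower-cased on read; any letter outside `a,t,c,g` is
#' preserved as `n` (with a warning when characters other than the usual
#' ambiguity codes are seen).  Records are keyed by the header token before
#' the first whitespace.
#'
#' @param path path to a (multi-record, wrapped or unwrapped) FASTA file.
#' @return named character vector, chromosome name -> sequence.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("FASTA format error at line 1: empty file: ", path)
  if (!startsWith(first, ">")) {
    stop("FASTA format error at line 1: expected '>' header in ", path)
  }
  set <- Biostrings::readBStringSet(path)
  seqs <- tolower(as.character(set))
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  cleaned <- gsub("[^atcgn]", "n", seqs)
  n_odd <- sum(vapply(seqs, function(s) lengths(regmatches(s, gregexpr("[^atcgn]", s))), integer(1)))
  if (n_odd > 0) {
    warning(n_odd, " non-atcgn letter(s) mapped to 'n'")
  }
  cleaned
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Extract a strand-aware subsequence from a genome
#'
#' Returns `genome[[chrom]][start:end)`; for a `-` interval, the reverse
#' complement, so the result always reads 5'->3' on the interval's strand.
#'
#' @param genome named character vector from [read_fasta()].
#' @param interval one-row interval `data.frame` (see [genomic_interval()]).
#' @return sequence string of length `end - start`.
#' @export
extract_sequence <- function(genome, interval) {
  validate_intervals(interval)
  stopifnot(nrow(interval) == 1L)
  chrom <- interval$chrom
  if (!chrom %in% names(genome)) {
    stop("coordinate error: unknown chromosome in interval ",
         chrom, ":", interval$start, "-", interval$end)
  }
  len <- nchar(genome[[chrom]])
  if (interval$start < 0L || interval$end > len) {
    stop("coordinate error: interval ", chrom, ":", interval$start, "-",
         interval$end, " outside chromosome of length ", len)
  }
  s <- substr(genome[[chrom]], interval$start + 1L, interval$end)
  strand <- interval$strand %||% "+"
  if (identical(strand, "-")) reverse_complement(s) else s
}

#' Promoter interval of a transcript
#'
#' The promoter is the `length` bases immediately upstream of the
#' transcription start site, read towards the TSS: a `+` transcript starting
#' at `s` has promoter `[s - length, s, +]`; a `-` transcript ending at `e`
#' has promoter `[e, e + length, -]`, whose extraction reverse-complements
#' so all promoters read in forward (5'->3') direction.
#'
#' A promoter that would run off the chromosome start is rejected with an
#' error, never clipped: downstream window arithmetic assumes promoters of
#' exactly `length` bases.
#'
#' @param transcript one-row transcript table with `chrom`, `start`, `end`,
#'   `strand` (and optionally `gene_id`, carried through).
#' @param length promoter length in bp (default 500).
#' @return one-row interval `data.frame`.
#' @export
promoter_interval <- function(transcript, length = 500L) {
  validate_intervals(transcript, require_strand = TRUE)
  stopifnot(nrow(transcript) == 1L, length > 0L)
  if (transcript$strand == "+") {
    start <- transcript$start - as.integer(length)
    if (start < 0L) {
      stop("truncation error: promoter of ", transcript$chrom, ":",
           transcript$start, " would underflow the chromosome start")
    }
    out <- genomic_interval(transcript$chrom, start, transcript$start, "+")
  } else {
    out <- genomic_interval(transcript$chrom, transcript$end,
                            transcript$end + as.integer(length), "-")
  }
  if (!is.null(transcript$gene_id)) out$gene_id <- transcript$gene_id
  out
}

#' Build the promoter set for a transcript table
#'
#' Deduplicates to one promoter per `gene_id`, keeping the transcript whose
#' TSS is most distal in the direction of transcription (smallest start on
#' `+`, largest end on `-`), then extracts the `length`-bp promoter
#' sequences.  Transcripts whose promoter would fall outside the chromosome
#' are dropped and counted in a message.
#'
#' @param transcripts data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param genome named character vector of chromosome sequences.
#' @param length promoter length in bp.
#' @return data.frame with one row per retained gene: `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (promoter coordinates) and `sequence`.
#' @export
promoters_from_transcripts <- function(transcripts, genome, length = 500L) {
  validate_intervals(transcripts, require_strand = TRUE)
  stopifnot(!is.null(transcripts$gene_id), all(nzchar(transcripts$gene_id)))
  keep <- unlist(lapply(split(seq_len(nrow(transcripts)), transcripts$gene_id),
                        function(idx) {
    tx <- transcripts[idx, , drop = FALSE]
    if (tx$strand[1] == "+") idx[which.min(tx$start)] else idx[which.max(tx$end)]
  }), use.names = FALSE)
  tx <- transcripts[sort(keep), , drop = FALSE]

  rows <- vector("list", nrow(tx))
  dropped <- 0L
  for (i in seq_len(nrow(tx))) {
    prom <- tryCatch(promoter_interval(tx[i, , drop = FALSE], length),
                     error = function(e) NULL)
    if (!is.null(prom)) {
      seq <- tryCatch(extract_sequence(genome, prom), error = function(e) NULL)
      if (!is.null(seq)) {
        prom$sequence <- seq
        rows[[i]] <- prom
        next
      }
    }
    dropped <- dropped + 1L
  }
  if (dropped > 0L) {
    message(dropped, " transcript(s) dropped: promoter outside chromosome bounds")
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), gene_id = character(),
                      sequence = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out[, c("gene_id", "chrom", "start", "end", "strand", "sequence")]
}

#' Read a peak table (BED3+ / narrowPeak-like TSV)
#'
#' Requires at least three columns `chrom`, `start`, `end` (0-based
#' half-open, no header or a header line starting with `chrom`/`#`).  Rows
#' with `start >= end` are rejected with a warning reporting the count.
#' Extra columns are retained.  The result is sorted by `(chrom, start)`.
#'
#' @param path path to the TSV.
#' @param tf_label label recorded in the `tf` column (e.g. `"SRE"`).
#' @return data.frame of intervals sorted by `(chrom, start)`; empty input
#'   yields an empty table.
#' @export
read_peaks <- function(path, tf_label = NA_character_) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      tf = character(), stringsAsFactors = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(empty)
  skip <- grepl("^(#|track|browser)", lines[1]) ||
    grepl("^chrom\\b", lines[1], ignore.case = TRUE)
  tab <- read.table(text = lines, sep = "\t", header = FALSE,
                    skip = as.integer(skip), stringsAsFactors = FALSE,
                    comment.char = "")
  if (nrow(tab) == 0L) return(empty)
  if (ncol(tab) < 3L) stop("peak table needs >= 3 columns (chrom, start, end): ", path)
  names(tab)[1:3] <- c("chrom", "start", "end")
  if (ncol(tab) > 3L) {
    names(tab)[-(1:3)] <- paste0("attr", seq_len(ncol(tab) - 3L))
  }
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  bad <- is.na(tab$start) | is.na(tab$end) | tab$start < 0L | tab$start >= tab$end
  if (any(bad)) {
    warning(sum(bad), " peak row(s) rejected (start >= end or unparsable)")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab$tf <- tf_label
  tab <- tab[order(tab$chrom, tab$start), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Read transcript coordinates from a BED file
#'
#' BED6 columns `chrom start end name score strand`; `name` is used as the
#' `gene_id`.
#'
#' @param path path to the BED file.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_transcripts <- function(path) {
  tab <- read_peaks(path)
  if (ncol(tab) < 6L + 1L) stop("transcript BED needs 6 columns: ", path)  # +1 for tf
  out <- data.frame(gene_id = as.character(tab$attr1), chrom = tab$chrom,
                    start = tab$start, end = tab$end,
                    strand = as.character(tab$attr3),
                    stringsAsFactors = FALSE)
  validate_intervals(out, require_strand = TRUE)
  if (any(!nzchar(out$gene_id))) stop("empty gene_id in ", path)
  out
}

## ---- conservation tracks ---------------------------------------------------

#' Construct a per-base conservation track
#'
#' Internal representation of a phyloP-like track: for each chromosome a
#' 0-based `offset` and a numeric vector of per-base `scores` (gaps inside
#' the covered span are `NA`).  Lookups outside coverage return `NA`, the
#' missing-value marker.
#'
#' @param chroms named list, chromosome -> `list(offset =, scores =)`.
#' @return object of class `conservation_track`.
#' @export
conservation_track <- function(chroms) {
  stopifnot(is.list(chroms), !is.null(names(chroms)))
  for (ch in chroms) stopifnot(is.numeric(ch$scores), ch$offset >= 0)
  structure(list(chroms = chroms), class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat("conservation_track over", length(x$chroms), "chromosome(s)\n")
  for (nm in names(x$chroms)) {
    ch <- x$chroms[[nm]]
    cat("  ", nm, ": [", ch$offset, ", ", ch$offset + length(ch$scores),
        ") ", sum(!is.na(ch$scores)), " scored bases\n", sep = "")
  }
  invisible(x)
}

#' Per-base scores over an interval
#'
#' @param track a [conservation_track()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return numeric vector of length `end - start`; `NA` where uncovered.
#' @export
conservation_slice <- function(track, chrom, start, end) {
  stopifnot(inherits(track, "conservation_track"), start >= 0, end > start)
  out <- rep(NA_real_, end - start)
  ch <- track$chroms[[chrom]]
  if (is.null(ch)) return(out)
  idx <- (start:(end - 1L)) - ch$offset + 1L
  ok <- idx >= 1L & idx <= length(ch$scores)
  out[ok] <- ch$scores[idx[ok]]
  out
}

#' Read a conservation track (wiggle fixedStep or bedGraph)
#'
#' Parsing is done by `rtracklayer::import`; the 1-based wiggle coordinates
#' are converted to the package's 0-based convention.
#'
#' @param path path to a `.wig` / `.bedGraph` file.
#' @param format `"wig"` or `"bedGraph"`; guessed from the extension by
#'   default.
#' @return a [conservation_track()].
#' @export
read_wiggle <- function(path, format = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedGraph" else "wig"
  }
  gr <- rtracklayer::import(path, format = format)
  chroms <- list()
  for (chrom in unique(as.character(GenomicRanges::seqnames(gr)))) {
    g <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
    start0 <- min(GenomicRanges::start(g)) - 1L   # to 0-based
    end0 <- max(GenomicRanges::end(g))
    scores <- rep(NA_real_, end0 - start0)
    for (i in seq_along(g)) {
      a <- GenomicRanges::start(g)[i] - 1L - start0 + 1L
      b <- GenomicRanges::end(g)[i] - start0
      scores[a:b] <- S4Vectors::mcols(g)$score[i]
    }
    chroms[[chrom]] <- list(offset = start0, scores = scores)
  }
  conservation_track(chroms)
}

#' Write a conservation track as wiggle fixedStep
#'
#' @param track a [conservation_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wiggle <- function(track, path) {
  stopifnot(inherits(track, "conservation_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(track$chroms)) {
    ch <- track$chroms[[nm]]
    # fixedStep is 1-based
    writeLines(sprintf("fixedStep chrom=%s start=%d step=1", nm, ch$offset + 1L), con)
    writeLines(format(ch$scores, trim = TRUE, digits = 6), con)
  }
  invisible(path)
}
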