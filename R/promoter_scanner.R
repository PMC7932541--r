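## Slide the trained classifier over 500-bp promoters, call SRE/NF-Y
## positives by the consecutive-window rule, and localise driving bases by
## averaged single-base occlusion.

#' Scan configuration
#'
#' @param promoter_length promoter length in bp (500).
#' @param window window length fed to the model (100).
#' @param scan_step step between scan windows (20; gives 21 windows on a
#'   500-bp promoter).
#' @param occlusion_step step between occlusion windows (5; gives 81
#'   windows).
#' @param call_run_length minimum number of consecutive qualifying windows
#'   for a positive promoter call (3).
#' @param call_threshold probability a window must exceed (strictly) to
#'   qualify (0.9).
#' @param call_rule `"each"` (default): every window of the run must exceed
#'   the threshold; `"mean"`: the mean over a run of `call_run_length`
#'   windows must exceed it (alternative reading, off by default).
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(promoter_length = 500L, window = 100L,
                        scan_step = 20L, occlusion_step = 5L,
                        call_run_length = 3L, call_threshold = 0.9,
                        call_rule = c("each", "mean")) {
  call_rule <- match.arg(call_rule)
  stopifnot(window <= promoter_length, scan_step >= 1L, occlusion_step >= 1L,
            call_run_length >= 1L, call_threshold > 0, call_threshold < 1)
  span <- promoter_length - window
  if (span %% scan_step != 0L || span %% occlusion_step != 0L) {
    stop("scan_step and occlusion_step must divide promoter_length - window")
  }
  structure(list(promoter_length = as.integer(promoter_length),
                 window = as.integer(window), scan_step = as.integer(scan_step),
                 occlusion_step = as.integer(occlusion_step),
                 call_run_length = as.integer(call_run_length),
                 call_threshold = call_threshold, call_rule = call_rule),
            class = "scan_config")
}

#' Cut a promoter into overlapping scan windows
#'
#' @param seq500 promoter sequence of exactly `config$promoter_length`
#'   bases.
#' @param config a [scan_config()].
#' @param step window step; defaults to `config$scan_step`.
#' @return data.frame with `offset` (0-based promoter coordinate of the
#'   window start) and `window` (sequence).
#' @export
window_promoter <- function(seq500, config = scan_config(),
                            step = config$scan_step) {
  stopifnot(length(seq500) == 1L)
  if (nchar(seq500) != config$promoter_length) {
    stop("promoter must be exactly ", config$promoter_length, " bases, got ",
         nchar(seq500))
  }
  offsets <- seq.int(0L, config$promoter_length - config$window, by = step)
  data.frame(offset = offsets,
             window = substring(seq500, offsets + 1L,
                                offsets + config$window),
             stringsAsFactors = FALSE)
}

#' Positive-call rule on a window probability profile
#'
#' Under the default rule a promoter is positive iff some run of at least
#' `call_run_length` consecutive windows each strictly exceeds
#' `call_threshold`; the longest qualifying run (first on ties) is
#' reported.  Under `call_rule = "mean"` a run of exactly
#' `call_run_length` windows whose mean exceeds the threshold suffices.
#'
#' @param probabilities per-window probabilities, scan order.
#' @param config a [scan_config()].
#' @return list with `call` (logical), `run_start`, `run_end` (1-based
#'   window indices of the qualifying run, `NA` if negative).
#' @export
call_positive <- function(probabilities, config = scan_config()) {
  stopifnot(length(probabilities) > 0L)
  L <- config$call_run_length
  if (config$call_rule == "each") {
    r <- rle(probabilities > config$call_threshold)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ok <- which(r$values & r$lengths >= L)
    if (length(ok) == 0L) {
      return(list(call = FALSE, run_start = NA_integer_, run_end = NA_integer_))
    }
    best <- ok[which.max(r$lengths[ok])]
    list(call = TRUE, run_start = starts[best], run_end = ends[best])
  } else {
    n <- length(probabilities)
    if (n < L) {
      return(list(call = FALSE, run_start = NA_integer_, run_end = NA_integer_))
    }
    means <- vapply(seq_len(n - L + 1L),
                    function(i) mean(probabilities[i:(i + L - 1L)]), numeric(1))
    if (!any(means > config$call_threshold)) {
      return(list(call = FALSE, run_start = NA_integer_, run_end = NA_integer_))
    }
    i <- which.max(means)
    list(call = TRUE, run_start = i, run_end = i + L - 1L)
  }
}

#' Scan one promoter
#'
#' @param model classifier accepted by [predict_proba()].
#' @param seq500 promoter sequence.
#' @param config a [scan_config()].
#' @param gene_id optional identifier carried into the profile.
#' @return list of class `scan_profile`: `gene_id`, `offsets`,
#'   `probabilities`, `call`, `run_start`, `run_end` (window indices).
#' @export
scan_promoter <- function(model, seq500, config = scan_config(),
                          gene_id = NA_character_) {
  win <- window_promoter(seq500, config)
  p <- predict_proba(model, win$window)
  cl <- call_positive(p, config)
  structure(list(gene_id = gene_id, offsets = win$offset, probabilities = p,
                 call = cl$call, run_start = cl$run_start,
                 run_end = cl$run_end),
            class = "scan_profile")
}

#' Scan a promoter table in one batch
#'
#' All windows of all promoters go through the model in a single call,
#' which is much faster than per-promoter scanning.
#'
#' @param model classifier accepted by [predict_proba()].
#' @param promoters data.frame from [promoters_from_transcripts()] (needs
#'   `gene_id`, `sequence`; `chrom`/`start`/`end`/`strand` are carried
#'   through when present).
#' @param config a [scan_config()].
#' @return data.frame with one row per gene: `gene_id`, `call`,
#'   `run_start`, `run_end`, `max_probability`, plus a `profiles` attribute
#'   holding the per-window probability matrix (genes x windows).
#' @export
scan_promoters <- function(model, promoters, config = scan_config()) {
  stopifnot(is.data.frame(promoters), nrow(promoters) > 0L)
  wins <- lapply(promoters$sequence, window_promoter, config = config)
  n_win <- nrow(wins[[1]])
  all_windows <- unlist(lapply(wins, `[[`, "window"), use.names = FALSE)
  p <- predict_proba(model, all_windows)
  pm <- matrix(p, nrow = nrow(promoters), ncol = n_win, byrow = TRUE)
  calls <- lapply(seq_len(nrow(promoters)),
                  function(i) call_positive(pm[i, ], config))
  out <- data.frame(
    gene_id = promoters$gene_id %||% as.character(seq_len(nrow(promoters))),
    call = vapply(calls, `[[`, logical(1), "call"),
    run_start = vapply(calls, `[[`, integer(1), "run_start"),
    run_end = vapply(calls, `[[`, integer(1), "run_end"),
    max_probability = apply(pm, 1, max),
    stringsAsFactors = FALSE)
  for (col in c("chrom", "start", "end", "strand")) {
    if (!is.null(promoters[[col]])) out[[col]] <- promoters[[col]]
  }
  attr(out, "profiles") <- pm
  attr(out, "offsets") <- wins[[1]]$offset
  out
}

#' Map called runs back to genomic coordinates (BED)
#'
#' The qualifying run of windows spans promoter coordinates
#' `[run_offset_start, run_offset_end + window)`; for a `-` promoter the
#' extracted sequence is the reverse complement of the genomic slice, so
#' promoter position `i` corresponds to genomic base `end - 1 - i`.
#'
#' @param scan result of [scan_promoters()] including genomic columns.
#' @param config the [scan_config()] used for the scan.
#' @return BED-like data.frame (`chrom`, `start`, `end`, `name`, `score`,
#'   `strand`) of called regions, 0-based half-open.
#' @export
scan_to_bed <- function(scan, config = scan_config()) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(scan)))
  offsets <- attr(scan, "offsets")
  called <- scan[scan$call, , drop = FALSE]
  if (nrow(called) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(), score = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  a <- offsets[called$run_start]                      # promoter coords
  b <- offsets[called$run_end] + config$window
  plus <- called$strand == "+"
  g_start <- ifelse(plus, called$start + a, called$end - b)
  g_end <- ifelse(plus, called$start + b, called$end - a)
  data.frame(chrom = called$chrom, start = as.integer(g_start),
             end = as.integer(g_end), name = called$gene_id,
             score = round(called$max_probability, 4),
             strand = called$strand, stringsAsFactors = FALSE)
}

#' Single-base occlusion of one window
#'
#' The window's probability is recomputed 100 times, each time zeroing one
#' base, i.e. setting its one-hot row to all-zero.  Because the encoded
#' matrix carries the window twice (forward rows 0-99, reverse complement
#' rows 100-199), occluding base `i` zeroes both row `i` and its mirror row
#' `199 - i`; zeroing only the forward row would leak the base through the
#' reverse-complement half.
#'
#' @param model an `sre_cnn` (occlusion needs code-level access, so
#'   function surrogates are not supported here).
#' @param window100 a 100-base window.
#' @return numeric vector of 100 probability losses,
#'   `loss_i = p(intact) - p(base i occluded)`; positive loss means the
#'   base supports the positive prediction.
#' @export
occlude_window <- function(model, window100) {
  stopifnot(inherits(model, "sre_cnn"), nchar(window100) == 100L)
  codes <- encode_codes(window100)
  occluded <- matrix(rep(codes[1, ], each = 101L), nrow = 101L)
  for (i in 1:100) {
    occluded[i + 1L, i] <- -1L
    occluded[i + 1L, 200L - i + 1L] <- -1L
  }
  storage.mode(occluded) <- "integer"
  p <- cpp_cnn_predict(model$weights, occluded)
  p[1] - p[-1]
}

#' Averaged single-base occlusion over a promoter
#'
#' Windows are cut at `occlusion_step` (5 bp) offsets; windows whose intact
#' probability strictly exceeds `call_threshold` are the "best" windows.
#' Their per-base occlusion losses are mapped to promoter coordinates and
#' averaged base-wise across all contributing windows.
#'
#' @param model an `sre_cnn`.
#' @param seq500 promoter sequence.
#' @param config a [scan_config()].
#' @return data.frame of class `occlusion_profile` with `position`
#'   (promoter coordinate), `mean_loss` and `n_windows` (contributing
#'   windows), restricted to covered positions.  If no window qualifies the
#'   profile is empty and carries a `diagnostic` attribute.
#' @export
averaged_occlusion <- function(model, seq500, config = scan_config()) {
  win <- window_promoter(seq500, config, step = config$occlusion_step)
  intact <- predict_proba(model, win$window)
  best <- which(intact > config$call_threshold)
  loss_sum <- numeric(config$promoter_length)
  n_win <- integer(config$promoter_length)
  for (i in best) {
    loss <- occlude_window(model, win$window[i])
    idx <- win$offset[i] + seq_len(config$window)
    loss_sum[idx] <- loss_sum[idx] + loss
    n_win[idx] <- n_win[idx] + 1L
  }
  covered <- n_win > 0L
  out <- data.frame(position = which(covered) - 1L,
                    mean_loss = loss_sum[covered] / n_win[covered],
                    n_windows = n_win[covered])
  class(out) <- c("occlusion_profile", "data.frame")
  if (length(best) == 0L) {
    attr(out, "diagnostic") <-
      sprintf("no window exceeded the %.2f probability threshold (max %.3f)",
              config$call_threshold, max(intact))
  }
  out
}
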