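## Pair SRE ChIP peaks with a nearby NF-Y peak and cut the +/-50 bp
## training windows; negatives come from control peaks far from any
## SRE/NF-Y signal.  Peaks are reduced to their centre points: windows are
## anchored +/- flank around a point summit.

#' Pairing configuration
#'
#' @param max_pair_distance maximum centre-to-centre distance (bp) for an
#'   SRE peak and an NF-Y peak to form a couple; the workflow constant is
#'   250 (strictly less than).
#' @param flank half-width of the training window around the SRE peak
#'   centre; 50 gives the 100-bp window.
#' @return a list of class `pairing_config`.
#' @export
pairing_config <- function(max_pair_distance = 250L, flank = 50L) {
  stopifnot(max_pair_distance > 0L, flank > 0L)
  structure(list(max_pair_distance = as.integer(max_pair_distance),
                 flank = as.integer(flank)),
            class = "pairing_config")
}

peak_centers <- function(peaks) as.integer(floor((peaks$start + peaks$end) / 2))

ensure_sorted_peaks <- function(peaks, what) {
  o <- order(peaks$chrom, peaks$start)
  if (!identical(o, seq_len(nrow(peaks)))) {
    warning(what, " peaks were not sorted by (chrom, start); sorting internally")
    peaks <- peaks[o, , drop = FALSE]
    rownames(peaks) <- NULL
  }
  peaks
}

#' Find SRE-NFY couples
#'
#' For every SRE peak with at least one NF-Y peak whose centre lies closer
#' than `max_pair_distance` (strict) on the same chromosome, emit one
#' couple keeping the nearest NF-Y peak.
#'
#' @param sre_peaks,nfy_peaks peak tables from [read_peaks()], sorted by
#'   `(chrom, start)` (unsorted input is sorted with a warning).
#' @param config a [pairing_config()].
#' @return data.frame with one row per couple: `chrom`, `sre_start`,
#'   `sre_end`, `sre_center`, `nfy_center`, `distance`.
#' @export
find_couples <- function(sre_peaks, nfy_peaks, config = pairing_config()) {
  validate_intervals(sre_peaks); validate_intervals(nfy_peaks)
  sre_peaks <- ensure_sorted_peaks(sre_peaks, "SRE")
  nfy_peaks <- ensure_sorted_peaks(nfy_peaks, "NFY")
  out <- list()
  for (chrom in unique(sre_peaks$chrom)) {
    sre <- sre_peaks[sre_peaks$chrom == chrom, , drop = FALSE]
    nfy <- nfy_peaks[nfy_peaks$chrom == chrom, , drop = FALSE]
    if (nrow(nfy) == 0L) next
    sc <- peak_centers(sre)
    nc <- sort(peak_centers(nfy))
    # nearest NFY centre via binary search on the sorted centres
    pos <- findInterval(sc, nc)
    left <- ifelse(pos >= 1L, nc[pmax(pos, 1L)], NA_integer_)
    right <- ifelse(pos < length(nc), nc[pmin(pos + 1L, length(nc))], NA_integer_)
    dl <- abs(sc - left); dr <- abs(right - sc)
    nearest <- ifelse(is.na(dr) | (!is.na(dl) & dl <= dr), left, right)
    dist <- abs(sc - nearest)
    keep <- !is.na(dist) & dist < config$max_pair_distance
    if (any(keep)) {
      out[[chrom]] <- data.frame(
        chrom = chrom,
        sre_start = sre$start[keep], sre_end = sre$end[keep],
        sre_center = sc[keep], nfy_center = as.integer(nearest[keep]),
        distance = as.integer(dist[keep]), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), sre_start = integer(),
                      sre_end = integer(), sre_center = integer(),
                      nfy_center = integer(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cut the 100-bp training window of one couple
#'
#' The window spans `[center - flank, center + flank)` around the SRE peak
#' centre, forward strand, lowercase.
#'
#' @param pair one-row couple from [find_couples()].
#' @param genome named character vector of chromosome sequences.
#' @param config a [pairing_config()].
#' @return one-row `data.frame` with `chrom`, `center`, `start`, `end`,
#'   `sequence`, `label` (1).
#' @export
pair_window <- function(pair, genome, config = pairing_config()) {
  stopifnot(nrow(pair) == 1L)
  center <- pair$sre_center
  iv <- genomic_interval(pair$chrom, center - config$flank, center + config$flank)
  seq <- extract_sequence(genome, iv)
  data.frame(chrom = pair$chrom, center = center, start = iv$start,
             end = iv$end, sequence = seq, label = 1L,
             stringsAsFactors = FALSE)
}

window_around_centers <- function(chrom, centers, genome, flank, label) {
  rows <- list(); skipped <- 0L
  for (i in seq_along(centers)) {
    iv <- tryCatch(genomic_interval(chrom[i], centers[i] - flank, centers[i] + flank),
                   error = function(e) NULL)
    seq <- if (is.null(iv)) NULL else
      tryCatch(extract_sequence(genome, iv), error = function(e) NULL)
    if (is.null(seq)) { skipped <- skipped + 1L; next }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom[i], center = centers[i], start = iv$start, end = iv$end,
      sequence = seq, label = label, stringsAsFactors = FALSE)
  }
  if (skipped > 0L) {
    message(skipped, " window(s) skipped: outside chromosome bounds")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), center = integer(),
                      start = integer(), end = integer(),
                      sequence = character(), label = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Training windows for all couples
#'
#' @param pairs couples from [find_couples()].
#' @param genome named character vector.
#' @param config a [pairing_config()].
#' @return data.frame of positive (label 1) windows; out-of-bounds windows
#'   are skipped with a message.
#' @export
pair_windows <- function(pairs, genome, config = pairing_config()) {
  out <- window_around_centers(pairs$chrom, pairs$sre_center, genome,
                               config$flank, 1L)
  out$seed_id <- if (nrow(out)) paste0(out$chrom, ":", out$center) else character(0)
  out
}

#' Build the negative window set from control peaks
#'
#' Control peaks whose centres lie at least `max_pair_distance` bp from
#' every SRE and NF-Y peak centre contribute one +/-flank window each
#' (label 0); controls nearer to real signal are excluded to avoid label
#' noise.
#'
#' @param control_peaks,sre_peaks,nfy_peaks peak tables.
#' @param genome named character vector.
#' @param config a [pairing_config()].
#' @return data.frame of negative windows.
#' @export
build_negative_set <- function(control_peaks, sre_peaks, nfy_peaks, genome,
                               config = pairing_config()) {
  if (nrow(control_peaks) == 0L) {
    return(window_around_centers(character(0), integer(0), genome,
                                 config$flank, 0L))
  }
  validate_intervals(control_peaks)
  keep <- logical(nrow(control_peaks))
  for (chrom in unique(control_peaks$chrom)) {
    sel <- control_peaks$chrom == chrom
    cc <- peak_centers(control_peaks[sel, , drop = FALSE])
    tf_centers <- sort(c(
      peak_centers(sre_peaks[sre_peaks$chrom == chrom, , drop = FALSE]),
      peak_centers(nfy_peaks[nfy_peaks$chrom == chrom, , drop = FALSE])))
    if (length(tf_centers) == 0L) { keep[sel] <- TRUE; next }
    pos <- findInterval(cc, tf_centers)
    dl <- ifelse(pos >= 1L, cc - tf_centers[pmax(pos, 1L)], Inf)
    dr <- ifelse(pos < length(tf_centers),
                 tf_centers[pmin(pos + 1L, length(tf_centers))] - cc, Inf)
    keep[sel] <- pmin(dl, dr) >= config$max_pair_distance
  }
  ctl <- control_peaks[keep, , drop = FALSE]
  window_around_centers(ctl$chrom, peak_centers(ctl), genome, config$flank, 0L)
}
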