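## Conservation-weighted data augmentation.  Each positive 100-bp seed
## window is copied many times; in each copy a fixed number of positions is
## mutated, positions drawn by roulette-wheel selection with wheel slices
## proportional to the INVERSE of the per-base conservation score, so the
## most conserved bases are the least likely to be touched.

#' Augmentation configuration
#'
#' @param mutations_per_copy number of distinct positions mutated in each
#'   copy (workflow constant 20).
#' @param copies_per_seed augmented copies per seed window.  100 copies per
#'   seed plus the originals is what turns 1,301 seeds into 131,401
#'   positives.
#' @param epsilon positive shift applied before inverting the scores so the
#'   wheel is well defined for negative (accelerated-evolution) phyloP
#'   values; also bounds the largest slice.
#' @param split_ratio train fraction of the train:validation split (3:1 ->
#'   0.75).
#' @param rng_seed integer seed making the whole augmentation a pure
#'   function of its inputs, or `NULL` to use the current RNG stream.
#' @return a list of class `augment_config`.
#' @export
augment_config <- function(mutations_per_copy = 20L, copies_per_seed = 100L,
                           epsilon = 0.1, split_ratio = 0.75,
                           rng_seed = NULL) {
  stopifnot(mutations_per_copy >= 0L, copies_per_seed >= 0L, epsilon > 0,
            split_ratio > 0, split_ratio < 1)
  structure(list(mutations_per_copy = as.integer(mutations_per_copy),
                 copies_per_seed = as.integer(copies_per_seed),
                 epsilon = epsilon, split_ratio = split_ratio,
                 rng_seed = rng_seed),
            class = "augment_config")
}

#' Roulette-wheel selection probabilities from conservation scores
#'
#' Weight of position i is `1 / (s_i - min(s) + epsilon)`, normalised to
#' sum 1: strictly decreasing in the score, defined for negative scores,
#' and collapsing to the uniform wheel when all scores are equal.  Missing
#' scores must be replaced (by 0) beforehand; an all-missing track falls
#' back to uniform weights with a warning.
#'
#' @param scores numeric vector of per-base conservation scores (`NA` =
#'   missing).
#' @param epsilon positive shift constant.
#' @return numeric vector of probabilities summing to 1.
#' @export
mutation_weights <- function(scores, epsilon = 0.1) {
  stopifnot(epsilon > 0)
  if (all(is.na(scores))) {
    warning("all conservation scores missing; using uniform mutation weights")
    return(rep(1 / length(scores), length(scores)))
  }
  scores[is.na(scores)] <- 0
  w <- 1 / (scores - min(scores) + epsilon)
  w / sum(w)
}

#' Mutate one copy of a seed window
#'
#' Exactly `mutations_per_copy` distinct positions are chosen by sequential
#' weighted draws without replacement (the wheel is renormalised after each
#' draw); each chosen base is replaced by one of its three alternatives
#' drawn uniformly, so every mutation changes the base.  `n` positions are
#' never selected.  If fewer eligible positions exist than mutations
#' requested, all eligible positions are mutated with a warning.
#'
#' @param seq a 100-base window over `{a,t,c,g,n}`.
#' @param weights per-position probabilities from [mutation_weights()].
#' @param config an [augment_config()] (only `mutations_per_copy` is used).
#' @return the mutated sequence string.
#' @export
mutate_copy <- function(seq, weights, config = augment_config()) {
  chars <- strsplit(seq, "")[[1]]
  stopifnot(length(weights) == length(chars))
  eligible <- which(chars != "n")
  m <- config$mutations_per_copy
  if (length(eligible) < m) {
    warning("only ", length(eligible), " eligible positions; mutating all of them")
    m <- length(eligible)
  }
  if (m == 0L) return(seq)
  # sample() with prob and replace = FALSE performs exactly the sequential
  # renormalised roulette-wheel draw
  pos <- eligible[sample.int(length(eligible), m, replace = FALSE,
                             prob = weights[eligible])]
  bases <- c("a", "t", "c", "g")
  for (p in pos) {
    alt <- bases[bases != chars[p]]
    chars[p] <- alt[sample.int(3L, 1L)]
  }
  paste(chars, collapse = "")
}

#' Augment a set of seed windows
#'
#' Output is the originals plus `copies_per_seed` mutated copies of each
#' seed: `|seeds| * (1 + copies_per_seed)` sequences, each carrying
#' provenance (`origin`, `seed_id`, `copy`).
#'
#' @param seeds data.frame of positive windows (columns `sequence`, `label`
#'   and optionally `seed_id`), e.g. from [pair_windows()].
#' @param tracks list of per-seed numeric score vectors (same length as the
#'   window), one per row of `seeds`; `NA` scores are treated as 0.
#' @param config an [augment_config()].
#' @return data.frame with columns `sequence`, `label`, `origin`
#'   (`"seed"`/`"augmented"`), `seed_id`, `copy`.
#' @export
augment_set <- function(seeds, tracks, config = augment_config()) {
  stopifnot(is.data.frame(seeds), length(tracks) == nrow(seeds))
  seed_ids <- seeds$seed_id %||% as.character(seq_len(nrow(seeds)))
  for (i in seq_len(nrow(seeds))) {
    if (length(tracks[[i]]) != nchar(seeds$sequence[i])) {
      stop("conservation track length mismatch for seed ", seed_ids[i])
    }
  }
  with_seed_opt(config$rng_seed, {
    out <- vector("list", nrow(seeds))
    for (i in seq_len(nrow(seeds))) {
      w <- mutation_weights(tracks[[i]], config$epsilon)
      copies <- character(config$copies_per_seed)
      for (k in seq_len(config$copies_per_seed)) {
        copies[k] <- mutate_copy(seeds$sequence[i], w, config)
      }
      out[[i]] <- data.frame(
        sequence = c(seeds$sequence[i], copies),
        label = seeds$label[i] %||% 1L,
        origin = c("seed", rep("augmented", config$copies_per_seed)),
        seed_id = seed_ids[i],
        copy = c(0L, seq_len(config$copies_per_seed)),
        stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

#' Split labelled samples into training and validation sets
#'
#' Random split stratified by label (3:1 by default), with both sets
#' shuffled; the split is reproducible from `config$rng_seed`.
#'
#' @param samples data.frame with a `label` column.
#' @param config an [augment_config()].
#' @return list with `train` and `validation` data.frames (disjoint,
#'   exhaustive).
#' @export
split_train_val <- function(samples, config = augment_config()) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0L)
  with_seed_opt(config$rng_seed, {
    train_idx <- unlist(lapply(split(seq_len(nrow(samples)), samples$label),
                               function(idx) {
      n_train <- round(length(idx) * config$split_ratio)
      idx[sample.int(length(idx), n_train)]
    }), use.names = FALSE)
    val_idx <- setdiff(seq_len(nrow(samples)), train_idx)
    train <- samples[train_idx[sample.int(length(train_idx))], , drop = FALSE]
    val <- samples[val_idx[sample.int(length(val_idx))], , drop = FALSE]
    rownames(train) <- rownames(val) <- NULL
    list(train = train, validation = val)
  })
}

#' Assemble the full training corpus from peaks, genome and conservation
#'
#' Convenience wrapper over the pairing, windowing, augmentation and
#' splitting steps: finds SRE-NFY couples, cuts the positive +/-50-bp
#' windows, augments them with conservation-weighted mutation, builds the
#' negative set from control peaks, and returns the stratified 3:1
#' train/validation split.
#'
#' @param genome named character vector of chromosome sequences.
#' @param sre_peaks,nfy_peaks,control_peaks peak tables (see
#'   [read_peaks()]).
#' @param conservation a [conservation_track()].
#' @param pairing a [pairing_config()].
#' @param augment an [augment_config()].
#' @return list with `train`, `validation` (data.frames with `sequence`,
#'   `label`, provenance columns) and `couples` (the pair table).
#' @export
build_training_set <- function(genome, sre_peaks, nfy_peaks, control_peaks,
                               conservation, pairing = pairing_config(),
                               augment = augment_config()) {
  couples <- find_couples(sre_peaks, nfy_peaks, pairing)
  pos <- pair_windows(couples, genome, pairing)
  tracks <- lapply(seq_len(nrow(pos)), function(i) {
    conservation_slice(conservation, pos$chrom[i], pos$start[i], pos$end[i])
  })
  aug <- augment_set(pos, tracks, augment)
  neg <- build_negative_set(control_peaks, sre_peaks, nfy_peaks, genome,
                            pairing)
  neg$origin <- "control"
  neg$seed_id <- paste0(neg$chrom, ":", neg$center)
  neg$copy <- 0L
  cols <- c("sequence", "label", "origin", "seed_id", "copy")
  corpus <- rbind(aug[, cols], neg[, cols])
  c(split_train_val(corpus, augment), list(couples = couples))
}
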