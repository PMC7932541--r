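## Self-contained synthetic inputs with the statistical structure the
## pipeline assumes: a mini-genome with planted SRE-like and CCAAT motifs
## at close spacing, peak tables centred (with jitter) on the planted
## motifs, a smooth-ish conservation track peaking on motifs, a
## transcriptome whose promoters carry planted couples for a configured
## fraction of genes, and GO groups with one deliberately enriched term.
## Truth tables are first-class outputs so recovery properties are
## assertable without re-deriving ground truth.

#' Fixture configuration
#'
#' Defaults are sized for the package's standard synthetic experiment:
#' enough peak slots for a few thousand training windows and a few hundred
#' promoters.
#'
#' @param n_chromosomes,chrom_length mini-genome geometry.
#' @param n_positive_pairs planted SRE+NFY couples.
#' @param n_control_peaks control peaks on motif-free background.
#' @param sre_motif,nfy_motif,sp1_motif planted motif strings (canonical
#'   SRE-1 consensus, CCAAT box, GC box; configuration values, not wired
#'   into any pipeline logic).
#' @param pair_spacing two integers: range of SRE-centre to NFY-centre
#'   distances in bp.  The default keeps both motifs inside one 100-bp
#'   training window.
#' @param motif_mutation_rate per-base probability of degrading a planted
#'   motif base.
#' @param peak_jitter maximum shift of a peak centre from its motif centre.
#' @param peak_halfwidth peak extent on each side of the centre.
#' @param n_genes number of genes in the synthetic transcriptome.
#' @param gene_positive_fraction fraction of genes with a planted couple in
#'   their promoter.
#' @param n_terms,genes_per_term GO group geometry.
#' @param enriched_positive_fraction fraction of positive genes in the one
#'   designated enriched term.
#' @param rng_seed integer seed; all fixture outputs are pure functions of
#'   this configuration.
#' @return a list of class `fixture_config`.
#' @export
fixture_config <- function(n_chromosomes = 2L, chrom_length = 400000L,
                           n_positive_pairs = 25L, n_control_peaks = 2475L,
                           sre_motif = "atcaccccac", nfy_motif = "ccaat",
                           sp1_motif = "gggcgg",
                           pair_spacing = c(10L, 35L),
                           motif_mutation_rate = 0.05,
                           peak_jitter = 10L, peak_halfwidth = 75L,
                           n_genes = 300L, gene_positive_fraction = 0.12,
                           n_terms = 40L, genes_per_term = 20L,
                           enriched_positive_fraction = 0.8,
                           rng_seed = 1L) {
  stopifnot(grepl("^[atcg]+$", sre_motif), grepl("^[atcg]+$", nfy_motif),
            length(pair_spacing) == 2L, pair_spacing[1] <= pair_spacing[2],
            pair_spacing[2] < 250L, motif_mutation_rate >= 0,
            motif_mutation_rate < 1, gene_positive_fraction >= 0,
            gene_positive_fraction <= 1, enriched_positive_fraction >= 0,
            enriched_positive_fraction <= 1)
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 chrom_length = as.integer(chrom_length),
                 n_positive_pairs = as.integer(n_positive_pairs),
                 n_control_peaks = as.integer(n_control_peaks),
                 sre_motif = sre_motif, nfy_motif = nfy_motif,
                 sp1_motif = sp1_motif,
                 pair_spacing = as.integer(pair_spacing),
                 motif_mutation_rate = motif_mutation_rate,
                 peak_jitter = as.integer(peak_jitter),
                 peak_halfwidth = as.integer(peak_halfwidth),
                 n_genes = as.integer(n_genes),
                 gene_positive_fraction = gene_positive_fraction,
                 n_terms = as.integer(n_terms),
                 genes_per_term = as.integer(genes_per_term),
                 enriched_positive_fraction = enriched_positive_fraction,
                 rng_seed = rng_seed),
            class = "fixture_config")
}

random_bases <- function(n) sample(c("a", "t", "c", "g"), n, replace = TRUE)

## write motif into a char vector, degrading bases at the configured rate
plant_motif <- function(chars, start0, motif, rate) {
  m <- strsplit(motif, "")[[1]]
  if (rate > 0) {
    hit <- runif(length(m)) < rate
    for (i in which(hit)) {
      alt <- setdiff(c("a", "t", "c", "g"), m[i])
      m[i] <- alt[sample.int(3L, 1L)]
    }
  }
  chars[start0 + seq_along(m)] <- m
  chars
}

#' Generate the mini-genome with planted SRE/NFY couples
#'
#' Background is uniform random sequence.  Non-overlapping slots on a
#' 300-bp grid receive either a planted couple (SRE motif at the slot
#' centre, CCAAT motif at a random spacing on a random side) or are
#' reserved as motif-free control slots; the grid guarantees control
#' centres stay at least 250 bp from every planted motif.
#'
#' @param config a [fixture_config()].
#' @return list of class `fixture_genome`: `genome` (named character
#'   vector), `truth` (data.frame of planted motif instances: `chrom`,
#'   `start`, `end`, `type`, `pair_id`, `spacing`), `control_centers`
#'   (data.frame `chrom`, `center`).
#' @export
make_genome <- function(config = fixture_config()) {
  with_seed_opt(config$rng_seed, {
    slot_step <- 300L
    chroms <- paste0("chr", seq_len(config$n_chromosomes))
    slots <- do.call(rbind, lapply(chroms, function(ch) {
      centers <- seq.int(150L, config$chrom_length - 150L, by = slot_step)
      data.frame(chrom = ch, center = centers, stringsAsFactors = FALSE)
    }))
    need <- config$n_positive_pairs + config$n_control_peaks
    if (nrow(slots) < need) {
      stop("genome too small: ", nrow(slots), " slots for ", need,
           " pairs + controls")
    }
    pick <- sample.int(nrow(slots), need)
    pair_slots <- slots[pick[seq_len(config$n_positive_pairs)], , drop = FALSE]
    ctl_slots <- slots[pick[-seq_len(config$n_positive_pairs)], , drop = FALSE]

    genome_chars <- lapply(setNames(chroms, chroms),
                           function(ch) random_bases(config$chrom_length))
    truth <- list()
    sre_len <- nchar(config$sre_motif); nfy_len <- nchar(config$nfy_motif)
    for (i in seq_len(nrow(pair_slots))) {
      ch <- pair_slots$chrom[i]; cen <- pair_slots$center[i]
      spacing <- sample(seq.int(config$pair_spacing[1], config$pair_spacing[2]), 1L)
      dir <- sample(c(-1L, 1L), 1L)
      sre_start <- cen - sre_len %/% 2L              # 0-based
      nfy_center <- cen + dir * spacing
      nfy_start <- nfy_center - nfy_len %/% 2L
      genome_chars[[ch]] <- plant_motif(genome_chars[[ch]], sre_start,
                                        config$sre_motif,
                                        config$motif_mutation_rate)
      genome_chars[[ch]] <- plant_motif(genome_chars[[ch]], nfy_start,
                                        config$nfy_motif,
                                        config$motif_mutation_rate)
      pid <- paste0("pair", i)
      truth[[length(truth) + 1L]] <- data.frame(
        chrom = ch, start = c(sre_start, nfy_start),
        end = c(sre_start + sre_len, nfy_start + nfy_len),
        type = c("sre", "nfy"), pair_id = pid, spacing = spacing,
        stringsAsFactors = FALSE)
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(chrom = character(), start = integer(), end = integer(),
                 type = character(), pair_id = character(),
                 spacing = integer(), stringsAsFactors = FALSE)
    structure(list(
      genome = vapply(genome_chars, paste, character(1), collapse = ""),
      truth = truth,
      control_centers = data.frame(chrom = ctl_slots$chrom,
                                   center = ctl_slots$center,
                                   stringsAsFactors = FALSE),
      config = config), class = "fixture_genome")
  })
}

#' Peak tables emulating the ChIP input
#'
#' One peak per planted motif instance, centred on the motif centre with a
#' uniform jitter of at most `peak_jitter` bp; control peaks sit on the
#' motif-free control slots.
#'
#' @param gt a `fixture_genome` from [make_genome()].
#' @param config the same [fixture_config()].
#' @return list with `sre`, `nfy`, `control` peak data.frames
#'   (`chrom`, `start`, `end`), each sorted by `(chrom, start)`.
#' @export
make_peaks <- function(gt, config = gt$config) {
  with_seed_opt(if (is.null(config$rng_seed)) NULL else config$rng_seed + 1L, {
    peak_of <- function(chrom, center) {
      jit <- sample.int(2L * config$peak_jitter + 1L, length(center),
                        replace = TRUE) - config$peak_jitter - 1L
      c2 <- as.integer(center + jit)
      out <- data.frame(chrom = chrom, start = c2 - config$peak_halfwidth,
                        end = c2 + config$peak_halfwidth,
                        stringsAsFactors = FALSE)
      out <- out[order(out$chrom, out$start), , drop = FALSE]
      rownames(out) <- NULL
      out
    }
    tr <- gt$truth
    sre <- tr[tr$type == "sre", , drop = FALSE]
    nfy <- tr[tr$type == "nfy", , drop = FALSE]
    list(sre = peak_of(sre$chrom, (sre$start + sre$end) %/% 2L),
         nfy = peak_of(nfy$chrom, (nfy$start + nfy$end) %/% 2L),
         control = peak_of(gt$control_centers$chrom,
                           gt$control_centers$center))
  })
}

#' Conservation track emulating phyloP
#'
#' Background scores are standard normal; every planted motif base is
#' shifted up by +3 (conserved), so conservation-weighted augmentation
#' should avoid exactly the planted motifs.
#'
#' @param gt a `fixture_genome`.
#' @param config the [fixture_config()].
#' @param shift score shift on motif bases.
#' @return a [conservation_track()] covering each chromosome end to end.
#' @export
make_conservation <- function(gt, config = gt$config, shift = 3) {
  with_seed_opt(if (is.null(config$rng_seed)) NULL else config$rng_seed + 2L, {
    chroms <- lapply(setNames(names(gt$genome), names(gt$genome)), function(ch) {
      scores <- rnorm(nchar(gt$genome[[ch]]))
      tr <- gt$truth[gt$truth$chrom == ch, , drop = FALSE]
      for (i in seq_len(nrow(tr))) {
        idx <- (tr$start[i] + 1L):tr$end[i]
        scores[idx] <- scores[idx] + shift
      }
      list(offset = 0L, scores = scores)
    })
    conservation_track(chroms)
  })
}

#' Synthetic transcriptome and GO annotation
#'
#' Appends one gene chromosome to the genome: each gene occupies a 1200-bp
#' slot with a 500-bp promoter immediately upstream of its TSS (strand
#' random).  A configured fraction of genes get an SRE+CCAAT couple planted
#' inside the promoter (in promoter reading orientation, so minus-strand
#' genes carry the reverse-complemented block on the template).  GO groups
#' sample genes uniformly, except one designated term assembled with an
#' elevated fraction of positive genes.
#'
#' @param gt a `fixture_genome` (its genome is extended).
#' @param config the [fixture_config()].
#' @return list: `genome` (extended), `transcripts` (data.frame `gene_id`,
#'   `chrom`, `start`, `end`, `strand`), `genes` (truth: `gene_id`,
#'   `positive`, `strand`, `sre_promoter_start`, `nfy_promoter_start`,
#'   `spacing`), `annotations` (a `go_annotations`), `enriched_term`,
#'   `expected` (expected contingency of the designated term).
#' @export
make_transcriptome_and_go <- function(gt, config = gt$config) {
  with_seed_opt(if (is.null(config$rng_seed)) NULL else config$rng_seed + 3L, {
    n <- config$n_genes
    slot <- 1200L
    gchrom <- "gchr1"
    chars <- random_bases(n * slot)
    gene_ids <- sprintf("G%04d", seq_len(n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    positive <- seq_len(n) %in%
      sample.int(n, round(n * config$gene_positive_fraction))
    sre_len <- nchar(config$sre_motif); nfy_len <- nchar(config$nfy_motif)

    tx <- data.frame(gene_id = gene_ids, chrom = gchrom,
                     start = integer(n), end = integer(n), strand = strand,
                     stringsAsFactors = FALSE)
    genes <- data.frame(gene_id = gene_ids, positive = positive,
                        strand = strand,
                        sre_promoter_start = NA_integer_,
                        nfy_promoter_start = NA_integer_,
                        spacing = NA_integer_, stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      s <- (i - 1L) * slot
      prom <- random_bases(500L)
      if (positive[i]) {
        spacing <- sample(seq.int(config$pair_spacing[1],
                                  config$pair_spacing[2]), 1L)
        dir <- sample(c(-1L, 1L), 1L)
        # keep the whole block away from the promoter edges
        lo <- 30L + max(0L, -dir * spacing)
        hi <- 460L - sre_len - max(0L, dir * spacing)
        sre_start <- sample(seq.int(lo, hi), 1L)
        sre_center <- sre_start + sre_len %/% 2L
        nfy_start <- sre_center + dir * spacing - nfy_len %/% 2L
        prom <- plant_motif(prom, sre_start, config$sre_motif,
                            config$motif_mutation_rate)
        prom <- plant_motif(prom, nfy_start, config$nfy_motif,
                            config$motif_mutation_rate)
        genes$sre_promoter_start[i] <- sre_start
        genes$nfy_promoter_start[i] <- nfy_start
        genes$spacing[i] <- spacing
      }
      if (strand[i] == "+") {
        tx$start[i] <- s + 500L; tx$end[i] <- s + 1000L
        chars[s + 1:500] <- prom
      } else {
        tx$start[i] <- s + 200L; tx$end[i] <- s + 700L
        chars[s + 700L + 1:500] <- rev(chartr("atcg", "tagc", prom))
      }
    }
    genome <- c(gt$genome, setNames(paste(chars, collapse = ""), gchrom))

    # GO groups
    term_ids <- sprintf("GO:%07d", seq_len(config$n_terms))
    enriched <- term_ids[1]
    pos_genes <- gene_ids[positive]; neg_genes <- gene_ids[!positive]
    k_pos <- min(round(config$genes_per_term * config$enriched_positive_fraction),
                 length(pos_genes))
    enr_genes <- c(sample(pos_genes, k_pos),
                   sample(neg_genes, config$genes_per_term - k_pos))
    pairs <- setNames(rep(enriched, length(enr_genes)), enr_genes)
    for (t in term_ids[-1]) {
      g <- gene_ids[sample.int(n, config$genes_per_term)]
      pairs <- c(pairs, setNames(rep(t, length(g)), g))
    }
    term_names <- setNames(c("designated enriched process",
                             paste("background process", seq_len(config$n_terms - 1L))),
                           term_ids)
    annotations <- go_annotations(pairs, term_names)
    expected <- list(pos_in = sum(enr_genes %in% pos_genes),
                     n_in = length(enr_genes),
                     pos_out = sum(positive) - sum(enr_genes %in% pos_genes),
                     n_out = n - length(enr_genes))
    list(genome = genome, transcripts = tx, genes = genes,
         annotations = annotations, enriched_term = enriched,
         expected = expected)
  })
}

#' Write a complete fixture directory
#'
#' Runs all generators and writes FASTA, peak TSVs, a fixedStep wiggle, a
#' transcript BED, GO annotation TSVs, the truth tables and a manifest
#' JSON.  Everything round-trips through the package's own readers.
#'
#' @param config a [fixture_config()].
#' @param outdir output directory (created).
#' @return invisibly, the in-memory bundle: `genome_truth`, `peaks`,
#'   `conservation`, `txgo`, `paths`.
#' @export
simulate_fixtures <- function(config = fixture_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  gt <- make_genome(config)
  peaks <- make_peaks(gt, config)
  cons <- make_conservation(gt, config)
  txgo <- make_transcriptome_and_go(gt, config)

  p <- function(...) file.path(outdir, ...)
  write_fasta(txgo$genome, p("genome.fa"))
  for (nm in c("sre", "nfy", "control")) {
    write.table(peaks[[nm]], p(paste0(nm, "_peaks.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  write_wiggle(cons, p("conservation.wig"))
  bed <- data.frame(txgo$transcripts$chrom, txgo$transcripts$start,
                    txgo$transcripts$end, txgo$transcripts$gene_id, 0,
                    txgo$transcripts$strand)
  write.table(bed, p("transcripts.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  ann <- data.frame(gene_id = rep(names(txgo$annotations$gene2terms),
                                  lengths(txgo$annotations$gene2terms)),
                    go_id = unlist(txgo$annotations$gene2terms,
                                   use.names = FALSE))
  write.table(ann, p("go_annotations.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(names(txgo$annotations$term_names),
                         txgo$annotations$term_names),
              p("go_names.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(gt$truth, p("truth_motifs.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(txgo$genes, p("truth_genes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(config), enriched_term = txgo$enriched_term,
         expected = txgo$expected,
         files = list(genome = "genome.fa", sre = "sre_peaks.tsv",
                      nfy = "nfy_peaks.tsv", control = "control_peaks.tsv",
                      conservation = "conservation.wig",
                      transcripts = "transcripts.bed",
                      annotations = "go_annotations.tsv",
                      term_names = "go_names.tsv")),
    p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(genome_truth = gt, peaks = peaks, conservation = cons,
                 txgo = txgo, outdir = outdir))
}
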