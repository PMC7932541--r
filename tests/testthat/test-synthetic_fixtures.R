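test_that("planted motifs sit exactly at their truth coordinates", {
  fc <- small_fixture_config(seed = 91L)
  gt <- make_genome(fc)
  expect_identical(nchar(gt$genome[["chr1"]]), fc$chrom_length)
  tr <- gt$truth
  expect_identical(nrow(tr), 2L * fc$n_positive_pairs)
  for (i in seq_len(nrow(tr))) {
    planted <- substr(gt$genome[[tr$chrom[i]]], tr$start[i] + 1L, tr$end[i])
    motif <- if (tr$type[i] == "sre") fc$sre_motif else fc$nfy_motif
    mism <- sum(strsplit(planted, "")[[1]] != strsplit(motif, "")[[1]])
    # per-base degradation rate 0.05 makes >4 mismatches in 10 bp implausible
    expect_lte(mism, 4L)
  }
  # pair spacing within the configured range
  sre <- tr[tr$type == "sre", ]; nfy <- tr[tr$type == "nfy", ]
  d <- abs(((sre$start + sre$end) %/% 2L) -
           ((nfy$start + nfy$end) %/% 2L)[match(sre$pair_id, nfy$pair_id)])
  expect_true(all(d >= fc$pair_spacing[1] & d <= fc$pair_spacing[2]))
  # pure function of the configuration
  expect_identical(make_genome(fc)$genome, gt$genome)
})

test_that("couple finding recovers planted pairs from the jittered peaks", {
  fc <- small_fixture_config(seed = 92L)
  gt <- make_genome(fc)
  peaks <- make_peaks(gt, fc)
  couples <- find_couples(peaks$sre, peaks$nfy)
  expect_gte(nrow(couples), ceiling(0.95 * fc$n_positive_pairs))
  # each recovered couple lies at a planted SRE (within the peak jitter)
  sre_truth <- gt$truth[gt$truth$type == "sre", ]
  centers <- (sre_truth$start + sre_truth$end) %/% 2L
  for (i in seq_len(nrow(couples))) {
    expect_lte(min(abs(centers - couples$sre_center[i])), fc$peak_jitter)
  }
  # no planted pairs -> no couples
  fc0 <- small_fixture_config(seed = 93L)
  fc0$n_positive_pairs <- 0L
  gt0 <- make_genome(fc0)
  p0 <- make_peaks(gt0, fc0)
  expect_identical(nrow(find_couples(p0$sre, p0$nfy)), 0L)
  # controls stay >= 250 bp from every planted motif centre
  all_centers <- (gt$truth$start + gt$truth$end) %/% 2L
  ctl_centers <- (peaks$control$start + peaks$control$end) %/% 2L
  for (cc in ctl_centers) expect_gte(min(abs(all_centers - cc)), 250L)
})

test_that("conservation peaks on motifs steer mutations away from them", {
  fc <- small_fixture_config(seed = 94L)
  gt <- make_genome(fc)
  cons <- make_conservation(gt, fc)
  expect_identical(length(cons$chroms$chr1$scores), fc$chrom_length)
  tr <- gt$truth
  on_motif <- unlist(lapply(seq_len(nrow(tr)),
                            function(i) (tr$start[i] + 1L):tr$end[i]))
  s <- cons$chroms$chr1$scores
  expect_gte(mean(s[on_motif]) - mean(s[-on_motif]), 2)

  # augmentation mutates motif bases far below the background rate
  peaks <- make_peaks(gt, fc)
  couples <- find_couples(peaks$sre, peaks$nfy)
  pos <- pair_windows(couples[1, ], gt$genome)
  track <- conservation_slice(cons, pos$chrom, pos$start, pos$end)
  aug <- augment_set(pos, list(track),
                     augment_config(copies_per_seed = 200L, rng_seed = 95L))
  base <- strsplit(pos$sequence, "")[[1]]
  rates <- rowMeans(vapply(aug$sequence[aug$origin == "augmented"],
                           function(x) strsplit(x, "")[[1]] != base,
                           logical(100)))
  motif_pos <- which(track > 2)     # the +3-shifted (planted) bases
  expect_gte(length(motif_pos), 10L)
  expect_lt(mean(rates[motif_pos]), mean(rates[-motif_pos]) / 2)
})

test_that("promoter planting respects strand and the configured fraction", {
  fc <- small_fixture_config(seed = 96L)
  gt <- make_genome(fc)
  txgo <- make_transcriptome_and_go(gt, fc)
  genes <- txgo$genes
  expect_identical(sum(genes$positive),
                   as.integer(round(fc$n_genes * fc$gene_positive_fraction)))
  proms <- promoters_from_transcripts(txgo$transcripts, txgo$genome)
  for (i in which(genes$positive)) {
    seq <- proms$sequence[proms$gene_id == genes$gene_id[i]]
    planted <- substr(seq, genes$sre_promoter_start[i] + 1L,
                      genes$sre_promoter_start[i] + nchar(fc$sre_motif))
    mism <- sum(strsplit(planted, "")[[1]] !=
                strsplit(fc$sre_motif, "")[[1]])
    expect_lte(mism, 4L)
  }
  # both strands are exercised and recovered identically
  expect_true(all(c("+", "-") %in% genes$strand[genes$positive]))
})

test_that("the designated GO term is recoverable from the truth labels", {
  hits <- 0L
  for (seed in 1:5) {
    fc <- small_fixture_config(seed = 100L + seed)
    gt <- make_genome(fc)
    txgo <- make_transcriptome_and_go(gt, fc)
    calls <- data.frame(gene_id = txgo$genes$gene_id,
                        call = txgo$genes$positive)
    uni <- build_universe(calls, txgo$annotations)
    res <- enrich_all(uni, txgo$annotations, min_term_size = 5L)
    if (res$go_id[1] == txgo$enriched_term) hits <- hits + 1L
    # expected counts recorded by the generator match the realised table
    ct <- contingency_counts(txgo$annotations$term2genes[[txgo$enriched_term]],
                             uni)
    expect_identical(ct$pos_in, txgo$expected$pos_in)
    expect_identical(ct$n_in, txgo$expected$n_in)
  }
  expect_gte(hits, 4L)
})

test_that("fixture files round-trip through the package readers", {
  outdir <- withr::local_tempdir()
  fc <- small_fixture_config(seed = 97L)
  bundle <- simulate_fixtures(fc, outdir)
  genome <- read_fasta(file.path(outdir, "genome.fa"))
  expect_identical(genome, bundle$txgo$genome)
  sre <- read_peaks(file.path(outdir, "sre_peaks.tsv"), "SRE")
  expect_identical(sre[, c("chrom", "start", "end")],
                   bundle$peaks$sre[, c("chrom", "start", "end")])
  cons <- read_wiggle(file.path(outdir, "conservation.wig"))
  expect_equal(cons$chroms$chr1$scores,
               bundle$conservation$chroms$chr1$scores, tolerance = 1e-4)
  tx <- read_transcripts(file.path(outdir, "transcripts.bed"))
  expect_identical(tx[, c("gene_id", "chrom", "start", "end", "strand")],
                   bundle$txgo$transcripts)
  ann <- read_go_annotations(file.path(outdir, "go_annotations.tsv"),
                             file.path(outdir, "go_names.tsv"))
  expect_setequal(names(ann$term2genes),
                  names(bundle$txgo$annotations$term2genes))
  manifest <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_identical(manifest$enriched_term, bundle$txgo$enriched_term)
})
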