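test_that("read_fasta lower-cases, maps ambiguity codes to n, keys by header token", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 some description", "ACGT", "acgTN", ">c", "ACGTN"), tf)
  suppressWarnings(g <- read_fasta(tf))
  expect_named(g, c("chr1", "c"), ignore.order = TRUE)
  expect_identical(unname(g["chr1"]), "acgtacgtn")
  expect_identical(unname(g["c"]), "acgtn")

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT"), bad)
  expect_error(read_fasta(bad), "line 1")
  empty <- withr::local_tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(read_fasta(empty), "line 1")
})

test_that("extract_sequence slices 0-based half-open and honours strand", {
  genome <- c(chr1 = "aacgtt")
  expect_identical(extract_sequence(genome, genomic_interval("chr1", 1, 4)), "acg")
  expect_identical(
    extract_sequence(genome, genomic_interval("chr1", 1, 4, "-")), "cgt")
  expect_identical(extract_sequence(genome, genomic_interval("chr1", 0, 6)),
                   "aacgtt")
  expect_error(extract_sequence(genome, genomic_interval("chr1", 2, 9)),
               "chr1:2-9")
  expect_error(extract_sequence(genome, genomic_interval("chr9", 0, 3)),
               "chr9")
})

test_that("extracted length equals end - start for random valid intervals", {
  withr::local_seed(1)
  genome <- c(chrX = paste(sample(c("a", "t", "c", "g", "n"), 500, TRUE),
                           collapse = ""))
  for (i in 1:50) {
    a <- sample(0:498, 1); b <- sample((a + 1):500, 1)
    s <- sample(c("+", "-"), 1)
    expect_identical(
      nchar(extract_sequence(genome, genomic_interval("chrX", a, b, s))),
      as.integer(b - a))
  }
})

test_that("promoter_interval follows the strand-specific upstream rule", {
  plus <- genomic_interval("chr1", 10000, 12000, "+"); plus$gene_id <- "g1"
  p <- promoter_interval(plus)
  expect_identical(p[, c("start", "end", "strand")],
                   data.frame(start = 9500L, end = 10000L, strand = "+"))
  minus <- genomic_interval("chr1", 20000, 22000, "-")
  m <- promoter_interval(minus)
  expect_identical(m[, c("start", "end", "strand")],
                   data.frame(start = 22000L, end = 22500L, strand = "-"))
  expect_identical(promoter_interval(plus, 100)$start, 9900L)
  underflow <- genomic_interval("chr1", 100, 500, "+")
  expect_error(promoter_interval(underflow), "truncation")
})

test_that("promoter_interval is strand-symmetric under reflection", {
  withr::local_seed(2)
  for (i in 1:25) {
    s <- sample(1000:5000, 1); e <- s + sample(100:1000, 1)
    L <- 10000L  # reflection point 2L: x -> 2L - x
    tx <- genomic_interval("c", s, e, "+")
    refl <- genomic_interval("c", 2L * L - e, 2L * L - s, "-")
    p <- promoter_interval(tx, 200)
    q <- promoter_interval(refl, 200)
    expect_identical(q$start, 2L * L - p$end)
    expect_identical(q$end, 2L * L - p$start)
  }
})

test_that("minus-strand promoter sequence reads 5'->3' toward the TSS", {
  # gene on '-' at [10,16): promoter is [16,22) reverse-complemented
  genome <- c(chr1 = paste0(strrep("a", 10), "cccccc", "gattac",
                            strrep("a", 10)))
  tx <- genomic_interval("chr1", 10, 16, "-"); tx$gene_id <- "g"
  prom <- promoter_interval(tx, 6)
  expect_identical(extract_sequence(genome, prom),
                   reverse_complement("gattac"))
})

test_that("read_peaks validates, sorts, rejects bad rows and keeps extras", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr2\t500\t700\tpeakA", "chr1\t900\t1100\tpeakB",
               "chr1\t100\t300\tpeakC", "chr1\t400\t350\tbadrow"), tf)
  expect_warning(p <- read_peaks(tf, "SRE"), "1 peak row")
  expect_identical(nrow(p), 3L)
  expect_identical(p$chrom, c("chr1", "chr1", "chr2"))
  expect_identical(p$start, c(100L, 900L, 500L))
  expect_identical(p$attr1, c("peakC", "peakB", "peakA"))
  expect_true(all(p$tf == "SRE"))

  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_identical(nrow(read_peaks(empty)), 0L)
})

test_that("transcript BED and promoter deduplication keep the distal TSS", {
  genome <- c(chr1 = paste(rep("acgt", 1000), collapse = ""))
  tx <- rbind(
    data.frame(gene_id = "gA", chrom = "chr1", start = 1000L, end = 2000L,
               strand = "+"),
    data.frame(gene_id = "gA", chrom = "chr1", start = 1400L, end = 2000L,
               strand = "+"),
    data.frame(gene_id = "gB", chrom = "chr1", start = 2500L, end = 3000L,
               strand = "-"),
    data.frame(gene_id = "gB", chrom = "chr1", start = 2500L, end = 3200L,
               strand = "-"))
  proms <- promoters_from_transcripts(tx, genome)
  expect_identical(nrow(proms), 2L)
  # gA: smallest start on '+'; gB: largest end on '-'
  expect_identical(proms$start[proms$gene_id == "gA"], 500L)
  expect_identical(proms$start[proms$gene_id == "gB"], 3200L)
  expect_true(all(nchar(proms$sequence) == 500L))

  # out-of-bounds promoters are dropped with a message, not clipped
  tx2 <- data.frame(gene_id = "gC", chrom = "chr1", start = 100L, end = 300L,
                    strand = "+")
  expect_message(p2 <- promoters_from_transcripts(rbind(tx, tx2), genome),
                 "dropped")
  expect_false("gC" %in% p2$gene_id)
})

test_that("conservation tracks round-trip through wiggle fixedStep", {
  withr::local_seed(3)
  track <- conservation_track(list(
    chrA = list(offset = 10L, scores = round(rnorm(50), 4)),
    chrB = list(offset = 0L, scores = round(rnorm(20, 2), 4))))
  tf <- withr::local_tempfile(fileext = ".wig")
  write_wiggle(track, tf)
  back <- read_wiggle(tf)
  expect_equal(back$chroms$chrA$offset, 10L)
  expect_equal(back$chroms$chrA$scores, track$chroms$chrA$scores,
               tolerance = 1e-6)
  expect_equal(back$chroms$chrB$scores, track$chroms$chrB$scores,
               tolerance = 1e-6)
  # slices outside coverage return the missing marker
  sl <- conservation_slice(back, "chrA", 5, 15)
  expect_true(all(is.na(sl[1:5])))
  expect_equal(sl[6:10], track$chroms$chrA$scores[1:5], tolerance = 1e-6)
  expect_true(all(is.na(conservation_slice(back, "chrZ", 0, 5))))
})
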