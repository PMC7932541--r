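# Shared helpers: small fixture configurations, random windows, and one
# memoised model trained on the standard synthetic experiment (reused by the
# scanning/occlusion tests and the acceptance suite so the expensive
# training happens once per run).

random_window <- function(n = 1L, len = 100L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("a", "t", "c", "g"), len, replace = TRUE), collapse = "")
  }, character(1))
}

small_fixture_config <- function(seed = 11L, ...) {
  fixture_config(n_chromosomes = 1L, chrom_length = 30000L,
                 n_positive_pairs = 20L, n_control_peaks = 40L,
                 n_genes = 40L, n_terms = 6L, genes_per_term = 10L,
                 gene_positive_fraction = 0.3, rng_seed = seed, ...)
}

.model_cache <- new.env(parent = emptyenv())

# The standard synthetic experiment: default fixture geometry (25 planted
# couples augmented 100x plus 2,475 controls -> 5,000 windows split 3:1),
# default model configuration.  Seeds fixed once for the whole suite.
fixture_model_bundle <- function() {
  if (!is.null(.model_cache$bundle)) return(.model_cache$bundle)
  fc <- fixture_config(rng_seed = 101L)
  gt <- make_genome(fc)
  peaks <- make_peaks(gt, fc)
  cons <- make_conservation(gt, fc)
  ts <- build_training_set(gt$genome, peaks$sre, peaks$nfy, peaks$control,
                           cons, pairing_config(),
                           augment_config(rng_seed = 202L))
  model <- train_cnn(build_model(model_config(rng_seed = 303L)),
                     ts$train, ts$validation)
  txgo <- make_transcriptome_and_go(gt, fc)
  .model_cache$bundle <- list(config = fc, genome_truth = gt, peaks = peaks,
                              conservation = cons, training = ts,
                              model = model, txgo = txgo)
  .model_cache$bundle
}

# constant-output classifier: every weight into the output unit zeroed
constant_model <- function(p_const = 0.5) {
  m <- build_model(suppressWarnings(
    model_config(n_filters = 8L, kernel_size = 3L, dense_units = 8L,
                 rng_seed = 5L)))
  m$weights$W4[] <- 0
  m$weights$b4 <- log(p_const / (1 - p_const))
  m
}
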