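# srescan

Detection of composite sterol-responsive-element (SRE) / NF-Y binding
regions in gene promoters with a 1-D convolutional network, for
regulatory-genomics work on cholesterol signalling.

SREBP transcription factors activate cholesterol-related genes through
SREs that almost never act alone: functional sites pair with NF-Y (CCAAT
box) and SP1 elements at short, variable spacings, in either order and on
either strand, which defeats single-consensus scanning.  `srescan` learns
the joint sequence signature instead:

1. **Couples.**  SRE ChIP peaks with an NF-Y peak centre closer than
   250 bp define the positive class; 100-bp windows
   `[centre − 50, centre + 50)` around the SRE summits are the training
   material, control-peak windows far (≥ 250 bp) from any SRE/NF-Y signal
   the negative class.
2. **Conservation-weighted augmentation.**  Each positive window is copied
   100× with exactly 20 point mutations per copy, positions drawn by
   roulette-wheel selection with slices ∝ 1/(s − min s + ε) over
   phyloP-like scores s — conserved (functional) bases are rarely touched.
   1,301 seed couples become 131,401 positives.
3. **Encoding.**  Window + reverse complement → 200 symbols, one-hot over
   (null, a, t, c, g): a `200 × 5` binary matrix.
4. **Classifier.**  conv → max-pool → conv → global max-pool →
   dense(64)/dropout → sigmoid, trained with Adam on batches of 512 in
   three epoch blocks (≤ 40/30/10) with early stopping on validation
   accuracy (patience 15/10/5).  Implemented from scratch in
   RcppArmadillo; gradients are verified against finite differences in the
   test suite.
5. **Scanning.**  Promoters are the 500 bases upstream of each TSS (read
   towards it, strand-aware).  The model slides in 20-bp steps (21 windows);
   a promoter is called positive when ≥ 3 *consecutive* windows score
   > 0.9.
6. **Occlusion.**  Zeroing one base at a time (both strand copies of it)
   yields per-base probability losses; averaging over 5-bp-stepped windows
   above the threshold localises the bases that drive a call.
7. **GO enrichment.**  For each Biological Process term, the odds ratio on
   the totals table `[[pos_in, pos_out], [n_in, n_out]]` — numerically the
   ratio of positive-promoter proportions in and out of the term — with the
   exact-conditional Fisher CI and p-value on the same table.

A synthetic-fixture generator (planted SRE/CCAAT couples, jittered peaks,
conservation tracks, transcriptome, GO groups, with truth tables) makes
the entire pipeline runnable and testable with no downloads.

## Worked example

The package's standard synthetic experiment end to end — 25 planted
couples augmented to 2,525 positives against 2,475 control windows, split
3:1, default model (64 filters, kernel 6):

```r
library(srescan)

fc     <- fixture_config(rng_seed = 101)
gt     <- make_genome(fc)
peaks  <- make_peaks(gt, fc)
cons   <- make_conservation(gt, fc)
corpus <- build_training_set(gt$genome, peaks$sre, peaks$nfy, peaks$control,
                             cons, pairing_config(),
                             augment_config(rng_seed = 202))
model  <- train_cnn(build_model(model_config(rng_seed = 303)),
                    corpus$train, corpus$validation)
evaluate_classifier(predict_proba(model, corpus$validation$sequence),
                    corpus$validation$label)
```

```
accuracy 0.967  precision 0.982  recall 0.952  F1 0.967  (TP 601 FP 11 FN 30 TN 608)
```

Scan the synthetic promoters and rank GO terms:

```r
txgo  <- make_transcriptome_and_go(gt, fc)
proms <- promoters_from_transcripts(txgo$transcripts, txgo$genome)
calls <- scan_promoters(model, proms)
table(planted = txgo$genes$positive[match(calls$gene_id, txgo$genes$gene_id)],
      called = calls$call)

universe <- build_universe(calls, txgo$annotations)
head(enrich_all(universe, txgo$annotations), 3)
```

```
       called
planted FALSE TRUE
  FALSE   259    5
  TRUE     10   26
```

```
      go_id                     go_name odds_ratio    ci_low   ci_high      p_value pos_in n_in
 GO:0000001 designated enriched process   5.626187 2.0007510 15.009721 0.0005188913      9   20
 GO:0000005        background process 4   2.638783 0.7126936  8.116339 0.0748531511      5   20
 GO:0000003        background process 2   1.470156 0.2630226  5.453855 0.4696302311      3   20
```

Reading: the model separates held-out windows at 0.967 accuracy; 26/36
promoters with a planted couple (and 5/264 without one) are called under
the ≥ 3-consecutive-windows > 0.9 rule — promoters whose planted SRE is
intact are essentially always found, degraded plants account for the
misses — and the deliberately enriched GO group tops the ranking with an
odds ratio of 5.6 at p ≈ 5 × 10⁻⁴ while background terms sit near 1.

The same machinery is exposed as a pipeline with resumable stages
(`simulate`, `pair`, `augment`, `train`, `scan`, `occlude`, `enrich`):

```sh
Rscript inst/scripts/srescan all --outdir out --seed 42
```

Real data drop in at the same seams: `read_fasta()`, `read_peaks()`
(BED3+/narrowPeak TSV), `read_wiggle()` (fixedStep/bedGraph),
`read_transcripts()` (BED6) and `read_go_annotations()`.

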