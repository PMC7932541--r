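---
title: "Detecting composite SRE/NF-Y promoter elements with srescan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting composite SRE/NF-Y promoter elements with srescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Sterol homeostasis is transcriptionally controlled by SREBP1/2, which bind
sterol-responsive elements (SREs) in promoters when intracellular
cholesterol drops.  Functional SREs rarely act alone: they co-occur with
NF-Y (CCAAT box) and SP1 sites in variable arrangements, orders and
strands, so no single consensus scan finds them reliably.  srescan
implements a workflow that side-steps explicit motif grammar: it learns
what ChIP-supported SRE+NF-Y neighbourhoods look like from sequence alone,
then scans promoters for regions that the learned model scores like those
neighbourhoods.

## Training material: SRE-NFY couples

Positives are defined coordinate-wise, not sequence-wise.  From SRE and
NF-Y ChIP peak tables, `find_couples()` keeps every SRE peak whose nearest
NF-Y peak centre lies strictly closer than 250 bp (`pairing_config()`).
Peaks are reduced to their centre points because the training windows are
cut around point summits: `pair_windows()` extracts the 100-bp window
`[centre - 50, centre + 50)` on the forward strand.  Anchoring on the SRE
(rather than the pair midpoint) keeps the detection target — the SRE — in
a consistent position while the NF-Y partner floats with its natural
spacing.  Negatives come from control ChIP peaks whose centres are at
least 250 bp away from every SRE and NF-Y centre; nearer controls are
discarded as likely label noise.

## Conservation-weighted augmentation

A 1,301-window positive class cannot balance a >100,000-window negative
class, so positives are expanded by mutation.  Mutations are *not* placed
uniformly: each position's chance of being selected follows a
roulette-wheel slice proportional to the inverse of its per-base
conservation score,

$$w_i = \frac{1}{s_i - \min(s) + \varepsilon},\qquad \varepsilon = 0.1,$$

normalised to sum to one.  PhyloP-style scores are negative at
fast-evolving sites, hence the min-shift; $\varepsilon$ keeps the weights
finite and bounds the largest slice.  Conserved bases — the presumed
functional core — are mutated rarely, so the expansion explores sequence
space around the motifs without destroying them.  Each of the 100 copies
per seed receives exactly 20 mutations at distinct positions (sequential
weighted draws without replacement; the replacement base is uniform over
the three alternatives, so every mutation changes the base).  With 1,301
seeds this gives $1{,}301 \times (1 + 100) = 131{,}401$ positives.  The
corpus is split 3:1 into training and validation, stratified by label so
that early stopping monitors a stable validation mix.

## Encoding

`double_sequence()` concatenates each 100-bp window with its reverse
complement; `one_hot()` maps the 200 symbols onto five binary columns in
the order (null, a, t, c, g), i.e. a = `01000`, t = `00100`, c = `00010`,
g = `00001`, with `n` and anything unexpected absorbed by the null code
`10000`.  The matrices are therefore 200x5 with unit row sums.  Presenting
both strands in one matrix lets a single forward pass detect a motif
regardless of strand.  The forward-then-reverse-complement order is a
package convention; the occlusion mirror rule below depends on it, so it
is fixed here and tested.

On the training path sequences are held as integer codes (0-4 per symbol)
and expanded to one-hot matrices batch by batch inside the gradient code —
the corpus is never materialised as matrices.

## The classifier

The network is a compact 1-D CNN implemented in RcppArmadillo:

* convolution, `n_filters` filters of width `kernel_size`, ReLU;
* max-pool of width 2;
* convolution, same filter count and width, ReLU;
* global max-pool over positions;
* dense layer of 64 units, ReLU; dropout 0.3;
* one sigmoid unit — the probability that the window harbours an
  SRE/NF-Y couple.

Binary cross-entropy loss, Adam updates (learning rate $10^{-3}$), batches
of 512.  The layer stack is a reconstruction (the tunable grid modulates
`n_filters` over {32, 64, 128} and `kernel_size` over {3, 6, 12}; defaults
64 and 6); gradients are verified against finite differences in the test
suite.  Global max-pooling makes the score position-invariant inside the
window, which is what lets a model trained on SRE-centred windows score
arbitrary promoter windows.

Training runs in three blocks of at most 40/30/10 epochs with
early-stopping patience 15/10/5 per block, monitoring validation
*accuracy* with min-delta 0; the best weights seen so far are restored at
each block boundary and at the end.  With identical data, configuration
and seed, training is reproducible on one machine (cross-device
bit-equality is not promised).

## Promoter scanning and the call rule

The promoter of a gene is the 500 bases immediately upstream of its TSS,
read 5'->3' towards it; minus-strand promoters are reverse-complemented on
extraction so all promoters read forward.  Promoters that would overrun a
chromosome edge are rejected, not clipped — the window grid assumes exactly
500 bases.  Genes with several transcripts keep the transcript whose TSS
is most distal in the direction of transcription, one promoter per gene.

`scan_promoters()` slides the 100-bp model window in steps of 20 bp:
offsets 0, 20, ..., 400, i.e. 21 windows covering the promoter exactly.  A
promoter is called positive when at least `call_run_length = 3`
consecutive windows each exceed `call_threshold = 0.9` (strict
inequality).  An alternative reading — the *mean* over a 3-window run
exceeding 0.9 — is available via `scan_config(call_rule = "mean")` but off
by default.  Called runs can be mapped back to strand-aware genomic BED
intervals with `scan_to_bed()`.

## Occlusion

To see *which bases* drive a positive score, `occlude_window()` recomputes
the window probability 100 times, each time zeroing one base, and reports
the loss `p(intact) - p(occluded)`.  Because the encoded matrix carries
the window twice (forward rows 0-99, reverse complement rows 100-199),
occluding base $i$ zeroes both row $i$ and row $199 - i$; zeroing only the
forward row would leak the base through the reverse-complement half and
roughly halve the saliency contrast.  `averaged_occlusion()` repeats this
over windows cut at 5-bp offsets (81 windows per promoter), keeps the
windows whose intact probability exceeds the call threshold, maps their
loss vectors to promoter coordinates and averages base-wise.  Positive
loss means the base supports the positive call.

## GO enrichment

Genes with at least one Biological Process annotation and a scanned
promoter form the universe; each is positive or negative by its promoter
call.  For a term with `n_in` universe genes of which `pos_in` are
positive (against `pos_out` of `n_out` outside), the enrichment statistic
lives on the totals table `[[pos_in, pos_out], [n_in, n_out]]`.  The
reported odds ratio is the exact-conditional MLE of the Fisher test on
that table — what epidemiology-style `oddsratio.fisher` functions return —
with its exact conditional 95% CI and two-sided p-value.  The plain
cross-product `(pos_in * n_out) / (pos_out * n_in)`, which is algebraically
the ratio of positive proportions, is reported as `sample_odds_ratio`; the
two agree to two decimals for tables of this shape.  Note this totals
table is *not* the conventional positive/negative contingency table; the
conventional odds ratio is emitted in its own clearly-labelled column
(`conventional_or`) and is typically several-fold larger.  No
multiple-testing correction is applied by default (Benjamini-Hochberg is
available behind `adjust = "BH"`); terms with fewer than 10 universe genes
are skipped.

## The synthetic fixture generator

`fixture_config()` + `simulate_fixtures()` build a fully self-contained
study: a uniform-background mini-genome with SRE ("atcaccccac") and CCAAT
("ccaat") motifs planted as couples on a 300-bp slot grid (so control
slots are always >= 250 bp from planted motifs), jittered peak tables, a
standard-normal conservation track with +3 on motif bases, a transcriptome
whose promoters carry planted couples for a configured fraction of genes
(on both strands, written in promoter reading orientation), and GO groups
with one designated term assembled from an elevated fraction of positive
genes.  Truth tables are first-class outputs, so recovery properties are
assertable without re-deriving ground truth, and every output is a pure
function of the configuration (seed included).

Sizing and defaults, chosen once as the package's standard experiment:

| parameter | default | why |
|---|---|---|
| planted couples | 25 | x(1+100) augmentation = 2,525 positives |
| control peaks | 2,475 | balances the corpus at 5,000 windows |
| pair spacing | 10-35 bp centre-to-centre | both motifs fit inside one 100-bp window, and a promoter-planted block is fully contained by 3-5 consecutive scan windows — the geometry the call rule needs |
| motif degradation | 0.05 per base | planted sites are variable, not letter-perfect |
| genes | 300, 12% with a planted pair | matches the out-group positive fraction scale of the published table |
| GO | 40 terms x 20 genes, designated term 80% positive | one clearly recoverable enrichment signal |

The 5,000-window corpus split 3:1 gives 3,750 training / 1,250 validation
windows; at this size the default model trains in minutes on one CPU and
reaches held-out accuracy ~0.96, and the whole pipeline (fixtures,
training, scanning 300 promoters, occlusion, enrichment) is what both the
test suite and `scripts/acceptance.R` execute.

What the generator does *not* emulate: genomic base composition and
repeats, peak-width and signal heterogeneity, the empirical SRE/NF-Y
spacing distribution, conservation autocorrelation, GO term overlap and
DAG structure.  Passing the synthetic experiment therefore shows the
machinery is correct and the method behaves as designed on data with the
assumed structure — not that the published genome-scale figures are
reproduced.

## Numerical choices and degenerate inputs

* Coordinates are BED-convention 0-based half-open everywhere internally;
  wiggle fixedStep input (1-based) is converted on read.
* `n` complements to `n`; any letter outside `atcgn` maps to `n` with a
  warning, and the encoder's null code absorbs it.  `n` positions are
  never selected for mutation.
* The window count per promoter is fixed by the geometry
  `(500 - 100)/20 + 1 = 21`; likewise 81 occlusion windows at step 5
  (100-bp windows at step 5 share 95% of their bases).
* The call rule uses strict `> 0.9`; a run of windows at exactly 0.9 is
  negative.  Ties between equally long qualifying runs keep the first.
* An all-missing conservation slice falls back to uniform mutation
  weights with a warning; missing scores are treated as 0.
* Zero cells in an enrichment table get a 0.5 continuity correction in
  the cross-product estimate and the row is flagged.
* Early stopping uses strict improvement (min-delta 0) of validation
  accuracy; `learning_rate = 0` is allowed (it freezes the model, which
  the tests use to pin down the stopping rule).

## Known limitations

* The exact layer stack of the original model is not published as text;
  the stack above is a faithful but unverifiable reconstruction, and the
  genome-scale performance figures are out of reach without the ENCODE
  corpus.
* The classifier trained on conservation-protected augmentation is sharp
  around the exact planted SRE: in the synthetic experiment, promoters
  whose planted SRE is intact are essentially always called, one degraded
  SRE base roughly halves the call probability, and two degraded bases
  suppress it.  Under the generator's 5% per-base degradation this puts
  planted-promoter sensitivity near 0.75 — the test suite measures this
  honestly rather than planting only letter-perfect sites.
* `occlude_window()` needs code-level access to the encoded matrix, so it
  accepts only the package's own models, not arbitrary classifier
  functions (the scanner accepts both).
* The enrichment CI/p provenance is exact-conditional on the totals
  table; the package does not attempt to reproduce any other interval
  construction.
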