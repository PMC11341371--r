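---
title: "Sequence-based enhancer-promoter interaction prediction with epiattn: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-based enhancer-promoter interaction prediction with epiattn: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Enhancers regulate transcription by contacting the promoters of their
target genes, often across large genomic distances. Experimental
detection of enhancer-promoter interactions (EPIs) by Hi-C-family
assays is expensive and cell-type-specific, which motivates
classifiers that predict, from DNA sequence alone, whether a given
(enhancer window, promoter window) pair interacts. `epiattn`
implements such a classifier — a k-mer-tokenized Transformer encoder
with a TextCNN head — together with the analyses that make it useful
to a regulatory genomicist: attention-based *de novo* motif discovery,
high-attention k-mer pair mining, and domain-adversarial transfer
between cell types. A fully seeded synthetic-data generator makes
every stage trainable and testable on one CPU core.

All coordinates in the package are 0-based half-open (BED convention).
Enhancer windows are 3,000 bp; promoter windows are 2,000 bp, spanning
1,500 bp upstream and 500 bp downstream of the TSS in transcription
orientation (minus-strand windows are mirrored and
reverse-complemented, so "upstream" always means upstream of
transcription). Windows that would overrun a contig are rejected
rather than padded, because padding characters would pollute the k-mer
vocabulary.

## Tokenization

Each element is decomposed into overlapping 6-mers at stride 1 (a
length-$L$ sequence gives $L-k+1$ tokens); 6 is the standard k for
DNA language models and leaves the vocabulary at a manageable
$4^6 = 4096$ words. Five special tokens — PAD, UNK, CLS, SEP, MASK —
occupy the lowest ids (0..4) in a fixed order so that serialized
vocabularies and checkpoints are stable across runs. An assembled
input is

```
[CLS] e_1 ... e_2995 [SEP] p_1 ... p_1995
```

which for the standard window sizes is 4,992 positions: CLS at 0-based
position 0, SEP at 2,996, the final promoter token at 4,991. K-mers
touching a non-ACGT base map to UNK rather than growing the
vocabulary; decoding (first base of each k-mer plus the tail of the
final one) verifies the mutual overlap of consecutive k-mers and
refuses inputs containing UNK, so corrupted token streams fail loudly
instead of producing chimeric sequences.

## Architecture

The encoder is BERT-style: learned token embeddings plus learned
absolute position embeddings feed a stack of Transformer encoder
layers (multi-head scaled-dot-product self-attention, post-layer-norm
residual blocks, GELU feed-forward). Three heads share the encoder
output:

* an MLM head (linear to vocabulary logits) for pre-training;
* a TextCNN classification head — three parallel 1-D convolutions of
  widths 4/5/6 (64 filters each by default) over the position-by-feature
  matrix, each max-pooled over positions, concatenated and passed
  through one fully connected layer to two logits. The convolutions
  run over *all* positions including specials, since the separator
  region demonstrably carries signal for this task;
* a domain discriminator (two-layer MLP) fed by the CLS-position
  vector (a mean-pooling switch exists) through a gradient reversal
  layer, used only during adversarial transfer.

The whole network is implemented in plain R matrix code over BLAS with
hand-derived backward passes; the test suite verifies every gradient
path against central finite differences at tolerance $10^{-3}$ on the
symmetrized relative error (typical error is below $10^{-5}$). There
is no framework dependency, and evaluation-mode forward passes are
bit-reproducible.

Default geometry is 4 layers, 4 heads, hidden width 128, feed-forward
256 — deliberately small enough to train on a CPU. A `"paper"` preset
(hidden 768, 12 heads) matches the geometry a GPU port would use.
Weights initialize as $\mathcal N(0, 0.02^2)$; dropout (default 0.1)
applies in training mode only.

## Training

**Pre-training.** The corpus builder tiles a genome into
non-overlapping chunks of at most 5,000 bp, splitting at N runs (no
chunk contains an N). Each step crops a random window of at most
`max_tokens` tokens, masks 15% of the non-special tokens — with the
standard 80/10/10 split among MASK / random token / unchanged — and
minimizes cross-entropy at the masked positions only. At least one
token is always masked (rounding guard for very short inputs).
Validation MLM loss on a held-out corpus fraction is checked
periodically, with plateau-based early stopping; a non-finite loss
aborts with a diagnostic rather than continuing to train a diverged
model.

**Class balancing.** EPI datasets are severely imbalanced (the
generator default is 10:1 negative:positive). Before fine-tuning, the
minority class is oversampled by *window-shift augmentation*: each
augmented record re-extracts both element windows from the genome at
an independent uniform offset in ±50 bp, so an augmented window shares
at least `length − 50` bases with its source but differs in phase and
flanks. Originals are always retained and provenance
(`augmented`, `source_record`) is tracked. Duplication-style balancing
can be had by setting `shift_bound = 0`.

**Fine-tuning.** Cross-entropy on the balanced training set with
decoupled-weight-decay Adam (lr $3\times10^{-4}$ by default at full
geometry, $10^{-3}$ in the desk benchmarks; linear warmup), evaluating
AUROC/AUPR/F1 on the validation set per epoch and keeping the weights
of the best validation-AUROC epoch. All randomness (shuffling,
dropout, masking) derives from one seed, so traces are exactly
reproducible on CPU.

**Adversarial transfer (DANN).** For cross-cell-type detection the
classifier loss $L_{class}$ is computed on labelled source records
only; a domain discriminator is trained to tell source from target on
both domains ($L_{domain}$); and the encoder receives the domain
gradient *through the gradient reversal layer* — identity forward,
$-\lambda \times$ gradient backward — which drives the encoder toward
features the discriminator cannot separate. A literal reading of the
combination $L_{class} - \lambda L_{domain}$ *and* a GRL would apply
the reversal twice; `epiattn` implements the standard DANN saddle
point (the GRL performs the reversal once; each head simply descends
its own loss) and logs all three terms per step, so either bookkeeping
convention can be audited from the trace. $\lambda$ defaults to a
constant 0.1; the usual ramp $2/(1+e^{-10p})-1$ over training progress
$p$ is available. Target labels, when present, are never consumed by
training — they exist for evaluation only.

## Attention analysis and motif discovery

For a record of interest the per-head attention matrices of the last
encoder layer are averaged (the mean of row-stochastic matrices is
row-stochastic). Per-token scores follow; note that the mean of a
row over *all* columns is identically $1/L$ for a row-stochastic
matrix, so the emitted-over-all-targets profile is constant by
construction. `token_profile()` therefore exposes both directions and
target restrictions, and the discovery pipeline defaults to attention
*received* (column means), the informative choice. Token scores are
decomposed to bases — each base averages the scores of the 1..k
tokens covering it — and normalized per element pair as
$(a_i - a_{\min})/a_{\max}$, i.e. shifted by the minimum and divided
by the maximum (not by the range). This lands in $[0,1]$ with the
argmin base at exactly 0; conventional min-max normalization is
available as an option.

High-attention regions are maximal runs of at least 6 bases above a
threshold. Because a single extreme position pins the divisor of the
shift-max normalization and compresses the rest of the profile toward
0, a fixed threshold is brittle across records; by default the driver
uses a per-record adaptive threshold at the 70th percentile of the
pair's normalized profile (a fixed threshold remains available). Each
region is kept with 4 bp of element context on both sides, because
called boundaries wobble by a few bases around the underlying signal.

Discovery then proceeds: (1) each positive-record region contributes
candidate *words* — all 6-mers of its padded context plus a window of
at most 12 bp around its attention peak; (2) every distinct word is
counted by substring containment in the same element role across the
full analysis universe, giving the hypergeometric upper-tail
enrichment $p$ of positives among containing pairs; (3) words passing
a Benjamini–Hochberg-adjusted cutoff of 0.005 with support in at
least 5 positive pairs survive — the BH step matters because
hundreds of candidate words are tested, and the support floor removes
sequences whose nominal significance rests on two or three pairs;
(4) surviving words merge greedily (substring, or best ungapped
overlap of at least 6 with at most 1 mismatch); (5) each cluster's
instances are located in the positive sequences, extended with
flanking context, and the consensus grows outward from the core while
the majority-base frequency stays at or above 0.55 — conserved context
(the rest of a motif only partially covered by seed words) survives,
random flanks stop the growth; the seed core itself is never shrunk,
which keeps low-complexity motifs with degenerate self-alignments
intact — after which clusters with agreeing extended consensi merge
and every member word is re-anchored on the final consensus by its
best near-full-length alignment (words that still mismatch are left
out of the matrix, since they reached the motif through a merge
chain); (6) the result is a set of position weight matrices with
support counts, exportable in MEME minimal format (round-trippable by
the bundled reader to $10^{-6}$). Consensus strings can carry a few
weakly-informative flank columns inherited from flank-bearing seed
words; the per-column frequencies in the PWM make the conserved core
obvious.

Regions whose words reached a supported, significant motif are labelled
*common*; the rest are *specific* — the same dichotomy used to
describe per-sequence motif composition. Positional preferences are
summarized by a midpoint histogram per role (count-conserving), which
on real promoters peaks near the TSS offset.

**K-mer pair mining.** For every record, each cross-segment cell
(enhancer-token row, promoter-token column) of the head-averaged
last-layer matrix at or above a threshold (default $10/L$, ten times
the uniform row weight) contributes one count to its (enhancer 6-mer,
promoter 6-mer) pair. Counts accumulate per class; the top 1,000 pairs
per class are compared, and pairs on the positive list absent from the
negative list are flagged exclusive — the candidates for
interaction-determining k-mer pairings.

## The synthetic generator

`generate_epi_dataset()` lays element windows (with flanks, so that
shift augmentation has headroom) on fresh contigs of an i.i.d.
background genome with controllable GC, plants mutated copies of an
enhancer-side and a promoter-side consensus motif at uniform random
interior positions of positive records, and leaves negatives as pure
background. Planted positions avoid the outermost $k-1$ bases so
every instance is fully covered by tokens. The truth table records
each planted instance and its position exactly, so recovery
assertions can be string-exact. Defaults: 200 positives, 2,000
negatives, 8-bp motifs planted with probability 1 and 5% per-base
substitution within instances, GC 0.5. `generate_domain_shift()`
derives a target cell line that reuses a chosen fraction of the
source motifs (at fraction 0.5, the enhancer motif is shared and the
promoter motif replaced) and may differ in background GC; target
labels are flagged evaluation-only.

What the generator does *not* emulate: genomic distance effects,
chromatin context, repeat structure, motif grammar beyond one planted
pair, or PWM-distributed instances (consensus + i.i.d. substitution
keeps truth strings exact; PWM sampling would be a natural extension).
Passing the benchmarks below therefore demonstrates that the
architecture, training loop and discovery pipeline work end to end —
not that the defaults are tuned for any real cell line.

## Desk-scale benchmark configuration

The package's benchmark experiments (`run_planted_benchmark()`,
`run_transfer_benchmark()`, `run_null_calibration()`) are sized to run
repeatedly on a single CPU core:

* windows of 180 bp (enhancer) and 120 bp (promoter), keeping the 3:2
  ratio of the full-scale convention — 292 token positions per pair;
* an encoder of 2 layers, 2 heads, hidden 32, feed-forward 64, TextCNN
  with 16 filters per width, no dropout;
* training with Adam at $10^{-3}$, batch 8, 2 epochs, capped at 200
  optimizer steps per epoch;
* planted-recovery data at the generator defaults (200/2,000, 8-bp
  motifs, 5% mutation); transfer at 100/400 per domain with GC 0.4 vs
  0.6 and shared fraction 0.5; null calibration at 100/500 with
  permuted labels, three seeds each.

These sizes are the package's reproducibility contract: large enough
that the planted signal is learnable and the enrichment statistics are
well-powered, small enough that the whole suite re-runs in minutes.
The full-scale geometry (3,000/2,000 bp, 4,992 tokens, hidden 128+) is
the package default everywhere outside the benchmark helpers and is
the configuration a GPU port would train.

## Numerical choices and edge cases

* Layer norm uses $\varepsilon = 10^{-5}$; GELU is exact
  ($x\,\Phi(x)$), not the tanh approximation.
* Softmax rows subtract the row maximum before exponentiation;
  attention masks PAD columns with $-\infty$ (at the fixed window
  sizes no PAD occurs, but variable-length batching remains possible).
* Adam uses $(\beta_1, \beta_2) = (0.9, 0.999)$, $\varepsilon=10^{-8}$,
  bias correction, decoupled weight decay (0 by default), and
  per-batch gradient averaging; ties in max-pooling argmaxes break to
  the first position so backward passes are deterministic.
* `normalize_profile()` refuses an all-zero profile (the normalization
  is undefined); `call_regions()` requires a threshold strictly inside
  (0, 1); the hypergeometric test validates its count invariants and
  `p(k=0) = 1` exactly.
* Dataset splits size groups by floor-then-distribute (largest
  fractional remainder first), so (0.8, 0.1, 0.1) of 100 records is
  exactly 80/10/10; the chromosome-aware mode assigns whole enhancer
  chromosomes greedily to the most under-filled split, preventing
  sequence leakage at the cost of approximate ratios.
* All stochastic steps route through one seeded RNG gate that restores
  the caller's RNG state, so library use never perturbs a user's
  random stream.

## Known limitations

* Pure-R training is two to three orders of magnitude slower than a
  GPU implementation; the full 4,992-token geometry is practical for
  inference and attention analysis, but training it end to end calls
  for the `"paper"`-preset port.
* Attention-based discovery inherits the biases of attention
  attribution: profiles concentrate mass on structural anchors
  (segment boundaries) as well as on content, which is precisely why
  the pipeline leans on adaptive thresholds and on the enrichment
  filter rather than on raw attention height. On weakly trained
  models, called regions can be mostly structural and discovery
  correctly returns nothing.
* The hypergeometric universe counts *pairs* (a sequence present in
  both elements of one pair counts once per role); alternative
  universes (elements, instances) would shift p-values.
* Low-complexity motifs (long homopolymer runs) align to themselves at
  many offsets, so their extended consensi are wider and fuzzier than
  those of high-complexity motifs — the same pathology every string
  motif finder faces, usually addressed upstream by repeat masking.
* The DANN benchmark measures a mean over three seeds; per-seed
  transfer gains on desk-scale data are noisy, as they are on real
  cross-cell-line panels.
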