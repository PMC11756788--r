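---
title: "Predicting and interpreting intron retention from open-chromatin sequence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and interpreting intron retention from open-chromatin sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Intron retention (IR) is the alternative-splicing outcome in which an intron
survives into the mature transcript. Splicing is predominantly
co-transcriptional, and chromatin state influences its outcome, so open
chromatin inside introns carries signal about whether those introns are
retained. `irchrom` implements a complete, testable pipeline around that
question: it labels DNase I hypersensitive sites (DHSs, 600 bp sequence
units) as IR or non-IR by overlap with retained introns, trains convolutional
sequence classifiers and chromatin-target-based classifiers to predict the
label, and interprets the fitted models — via integrated-gradients
attribution mapped to TF motifs, and via signed logistic-regression weights
over chromatin targets.

Real genome-scale inputs (reference annotation, DNase I-seq peak atlases,
RNA-seq IR calls, pre-trained chromatin models) are deliberately out of
scope. Instead a first-class synthetic-data module generates every input
with known ground truth, which turns each downstream claim ("the attribution
pipeline finds the causal motif") into a checkable statement.

## Dataset construction

Labeling follows a two-phase procedure with BED semantics (0-based,
half-open) throughout:

* **Annotation phase** — a DHS is IR if it overlaps a retained intron.
  The overlap of `[a,b)` and `[c,d)` is `max(0, min(b,d) - max(a,c))`. The
  source procedure says only "overlap" for this phase, so the threshold
  defaults to 1 bp; it is a config key (`min_overlap`), not a constant.
* **RNA-seq phase** — negatives overlapping an RNA-seq-derived retained
  intron by **at least 500 bp** are relabeled IR, and new DHSs passing the
  same rule are appended. Relabeling is monotone: the IR count never
  decreases, and totals obey an exact accounting identity
  (`dhs_summary()`), which the tests pin to the published event table
  (16,231 + 4,694 IR and 55,193 − 126 non-IR events; 151,984 sequences
  after augmentation).

Redundancy between partitions is removed with an in-package greedy
clustering (`reduce_redundancy()`): sequences visited longest-first (ties
broken lexicographically — determinism matters more than the particular
order), each joining the first cluster whose representative it matches at ≥
80% ungapped identity over the best offset on either strand. This replaces
an external clustering binary while keeping the threshold semantics; a
pre-computed cluster assignment can be passed straight to
`split_dataset()`. Splits assign whole clusters to train/validation/test
(80/10/10), so no test sequence has a near-duplicate in training; sizes land
within one cluster of the target fractions.

Reverse-complement augmentation doubles the data (original block, then
complement block). The whole-dataset totals above reflect augmenting every
partition; for model evaluation the analysis scripts augment the training
partition only, since evaluating on complements of test sequences duplicates
test information. One-hot encoding is a 4 × N binary matrix in fixed row
order A, C, G, T; `N` columns are all-zero, so they contribute nothing to
convolution activations.

## Models

No deep-learning framework is available in this R stack, and the
interpretation stage needs input gradients, so the package carries its own
small differentiable-network layer (`nn_model()` and friends): im2col
convolutions executed as BLAS matrix products, batch normalisation, ReLU /
GELU, max pooling, residual blocks, attention pooling, and dense layers,
each with an explicit backward pass. Forward/backward correctness is tested
against finite differences (tolerance 1e-4; observed agreement is ~1e-10).

* **Basset-like** (`basset_like()`): three conv/batch-norm/ReLU/max-pool
  blocks, then three dense layers ending in one sigmoid unit — the classic
  open-chromatin peak classifier.
* **Basenji-like** (`basenji_like()`): a linear convolutional stem, six
  blocks pairing linear convolutions with GELU non-linearities (the first
  blocks downsample), three dilated convolutional blocks with residual skip
  connections and dilation doubling per block, then the fine-tuning head.
* **Fine-tuning head** (`finetune_head()`): convolution → attention pooling
  (a learned per-position score, softmaxed over positions, weighting a sum
  of feature vectors) → dense layer → sigmoid. Two modes: `"block"` (the
  full head) and `"replace"` (flatten straight into one sigmoid unit,
  emulating swapping a pre-trained model's classification layer). Backbones
  are adapter slots behind `check_backbone()` — a miniature two-block
  embedder stands in for large pre-trained chromatin models, whose weights
  are not shipped; `frozen = TRUE` excludes backbone parameters (and their
  normalisation statistics) from training, and the tests assert
  bit-identical backbone parameters afterwards.
* **Targets classifiers**: `logistic_targets_model()` is a single
  dense+sigmoid unit trained through the same protocol with the
  class-rebalancing sampler and weak L2 (1e-4 — the source states no
  regularisation; a weak ridge stabilises the weights that the ranking
  interprets). `gbdt_targets_model()` fits leaf-wise gradient-boosted trees
  (xgboost, `grow_policy = "lossguide"`, 50 leaves, unlimited depth, 1000
  trees, class reweighting) mirroring the published boosted-trees settings.
  `subset_targets()` slices the targets matrix by group (TF / HM / ACC);
  group sizes live in metadata files, never in code, because the source
  reports two slightly different histone-mark counts.

The head's channel widths are unstated in the source; defaults
(`conv_channels = 128`, `kernel = 8`, `dense_units = 64`) are sized for
desk-scale experiments and are configurable.

## Training protocol

`fit()` implements: binary cross-entropy (probabilities clipped at 1e-7),
SGD with momentum 0.95 or AdamW (decoupled weight decay, default 0.01), a
schedule that warms up linearly from `warmup_begin_lr` to `max_lr` and
decays to `final_lr` along a cosine (`lr_at()`; stepped per optimiser step,
since the parameter names speak of steps, not epochs), early stopping after
`patience` epochs without strict validation-loss improvement (ties do not
reset the counter; `min_delta` defaults to 0), and restoration of the
best-epoch weights at exit — the source is silent on restoration, and
restoring is the reproducible choice. Epoch caps follow the published
protocol: 100 epochs / patience 10 for the CNNs, 1000 / 50 for the targets
classifiers. `imbalanced_sampler()` draws indices with replacement with
per-class probability inversely proportional to frequency, making the
expected per-epoch class balance 50/50.

One practical note on optimisation: AdamW's per-coordinate step is bounded
by roughly the learning rate, so with few optimiser steps (small data, few
epochs) a peak rate of 1e-3 cannot move first-layer filters far enough to
form motif detectors, and the network memorises instead. The desk-scale
experiments therefore use `max_lr = 0.05` with early stopping; the
validation loss, not the schedule, decides when to stop. At that peak rate
an unlucky initialisation occasionally lands the network in a dead
constant-output regime it cannot leave; `fit_with_restarts()` trains up to
three seeded attempts, keeps the best-validation one, and stops as soon as
an attempt clearly beats the trivial constant predictor. This is the
training entry point the experiments use.

## Evaluation

`roc_auc()` sweeps thresholds over distinct score values in descending
order (ties grouped) and integrates by trapezoid — exactly the Mann–Whitney
pair statistic with ties counted half, which the tests verify by exhaustive
pair counting. `pr_auc()` uses the step-wise (right-continuous) rule
`sum((R_i − R_{i−1}) · P_i)`; trapezoids over-estimate PR area, and the
step rule makes numbers comparable across runs. With constant scores the PR
area equals the positive prevalence.

## Interpretation

`integrated_gradients()` implements the right-Riemann approximation of the
attribution path integral from an all-zeros one-hot baseline (the
conventional "no sequence" reference; the source does not state one). The
completeness axiom `sum(IG) = f(x) − f(baseline)` is verified numerically:
the discretisation error shrinks with the step count and is under 1% of the
output span at 200 steps; 50 steps is the working default.

The downstream statistic follows the published thresholds exactly:

* sequences kept when the model gives their **true** class probability
  > 0.7, applied symmetrically (IR kept if `p > 0.7`, non-IR if
  `1 − p > 0.7`);
* a position is a **hot spot** when its attribution at the observed base
  exceeds 70% of the per-sequence maximum. Signs are preserved — the rule is
  implemented as written, so an all-non-positive attribution map yields no
  hot spots; `abs_attr` switches to magnitude mode. The extraction is
  invariant to positive rescaling;
* a motif **matches** a hot spot when any window of the motif's width, on
  either strand, covering the position scores at least 80% of the motif's
  maximum log-odds. Window extent is unstated in the source; all covering
  windows is the most permissive reading. Scoring is log-odds against the
  background (pseudocount 0.01 per PFM cell; uniform background unless one
  is supplied), with the per-motif maximum computed from the same log-odds
  matrix;
* the **enrichment score** of a motif is the fraction of IR hot spots it
  matches minus the fraction of non-IR hot spots, in [−1, 1], ranked
  descending with ties broken by motif id. Significance comes from a
  permutation null that shuffles hot-spot class labels
  (`enrichment_permutation()`); permuted scores are centred at zero.

`rank_lr_targets()` orders targets by signed logistic weight. One protein
can occupy several ranks (multiple cell types or conditions per protein);
`top_bottom_proteins()` reports proteins appearing in both the top-k and
bottom-k lists, the signature of factors that can push splicing either way
depending on context.

## The synthetic generators

`simulate_annotation()` lays introns with one embedded DHS each on a
synthetic chromosome, so the fraction of DHSs overlapping retained introns
is exact by construction. `plant_motif_sequences()` plants PWM-sampled motif
instances (uniform offset, random strand, never overlapping each other) into
i.i.d. background of configurable GC content — the simplest background under
which PWM log-odds is well defined, and non-overlap keeps hot-spot ground
truth unambiguous. `simulate_targets()` draws a targets matrix uniform on
[0, 1] and labels from `Bernoulli(sigmoid(w·x + b))` with a known sparse
`w`; the bias centres the average logit at zero. `simulate_pwm_library()`
produces sharp synthetic motifs (~94% consensus probability per column,
default width 12), comparable in information content to well-characterised
TF motifs — weak motifs in short windows make even the oracle PWM scan
non-separable, which would test the fixture rather than the method.

Every generator derives its own RNG stream from the user seed via
`derive_seed()` (a fixed integer hash), so partial re-runs reproduce
identical draws, and equal seeds give byte-identical FASTA/BED output.

What the generators do **not** emulate: splice-site sequence signal, gene
structure, read-level RNA-seq noise, correlated chromatin profiles, or the
long-range dependencies that motivate dilated and attention architectures.
Passing tests on this synthetic data demonstrates that the machinery —
labeling arithmetic, training, attribution, scanning, ranking — does what it
claims with known ground truth; it does not certify accuracy on real DHS
data.

## Problem sizes and numerical choices

The shipped experiments are sized for a single CPU: the motif-recovery study
uses 2 × 1000 sequences of 300 bp with one causal motif (planting 0.9 IR /
0.05 non-IR) among 9 decoys, a Basset-style classifier (~37k parameters,
reverse-complement-augmented training partition, up to 12 epochs), IG at 50
steps on a seeded subsample of up to 250 confidently-predicted sequences per
class, and 1000 permutations. Enrichment is a fraction, so subsampling
attribution sequences changes its precision, not its estimand. Because the
planted sequences are i.i.d. background, their pairwise identity sits far
below the 80% threshold and each sequence is its own redundancy cluster;
the clustering path itself is verified separately against a brute-force
oracle at small n. The architecture-comparison study (analysis stage 3) and
the unit tests use 120–150 bp sequences: every architecture — including the
deep Basenji-style stack, which needs more optimisation budget than the
desk scale affords at 300 bp — trains reliably there, and the comparison is
about architectures, not sequence length. The frozen-backbone variant in
stage 3 freezes an *already trained* embedder and retrains a fresh head;
freezing a random embedder is a much weaker baseline and is reported as
such where it appears.

Numerical details worth knowing: batch-norm uses eps 1e-5 and running-stat
momentum 0.1 (frozen layers keep their statistics); weight initialisation is
seeded He-uniform for convolutions and Glorot-uniform for dense layers;
`bce_loss` clips probabilities at 1e-7; a NaN training loss aborts with a
diagnostic rather than continuing silently.

## Limitations

The network layer is plain R + BLAS: adequate for the shipped problem sizes,
not for genome-scale training. Pre-trained chromatin backbones are contract
slots, not shipped weights, so "fine-tuning" here always starts from the
miniature embedder. The greedy clustering is quadratic and meant for
datasets up to a few thousand sequences. Tokenised language-model backbones
are out of scope entirely.
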