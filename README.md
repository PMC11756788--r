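# irchrom

Chromatin-aware prediction and interpretation of intron retention (IR) from
open-chromatin sequence.

Splicing is largely co-transcriptional, and chromatin state influences its
outcome. This package asks how much of that signal is readable from the
sequence of DNase I hypersensitive sites (DHSs) inside introns: 600 bp
open-chromatin sequences are labeled IR / non-IR by overlap with retained
introns, convolutional classifiers and chromatin-target classifiers are
trained to predict the label, and the fitted models are interpreted — by
integrated-gradients attribution mapped to TF motifs, and by signed
logistic-regression weights over chromatin-state targets.

The package is organised as an analysis workflow over a fully tested
library. Real genome-scale inputs are replaced by a first-class
synthetic-data module with known ground truth, so every stage of the
pipeline is verifiable end to end.

## What is inside

* **Synthetic data** — `simulate_annotation()` (genome + retained-intron +
  DHS intervals as FASTA/BED), `plant_motif_sequences()` (class-conditional
  PWM planting with a full plant log), `simulate_targets()` (chromatin-target
  matrix from a known sparse logistic model), `simulate_pwm_library()`
  (JASPAR-format motifs).
* **Dataset construction** — overlap labeling (`label_dhs()`), RNA-seq
  relabeling at ≥ 500 bp (`relabel_with_rnaseq()`), greedy redundancy
  clustering at 80% identity (`reduce_redundancy()`), cluster-aware 80/10/10
  splitting (`split_dataset()`), reverse-complement augmentation and one-hot
  encoding; `dhs_summary()` carries the exact event-count arithmetic.
* **Models** — `basset_like()` (3 conv + 3 dense), `basenji_like()` (linear
  stem, GELU conv blocks, residual dilated convolutions), `finetune_head()`
  (conv → attention pooling → dense → sigmoid over any backbone satisfying
  `check_backbone()`, with frozen and head-replacement modes),
  `logistic_targets_model()` and `gbdt_targets_model()` on target matrices,
  `subset_targets()` for TF / HM / ACC groups. All sequence models run on an
  in-package differentiable network layer (`nn_model()`) with exact
  backward passes — which is what makes integrated gradients possible here.
* **Training** — `fit()` with binary cross-entropy, AdamW / SGD-momentum,
  warmup + cosine schedule (`lr_at()`), validation-loss early stopping
  (`early_stopper()`), class-rebalancing sampling (`imbalanced_sampler()`),
  best-epoch weight restoration.
* **Evaluation** — `roc_auc()` / `pr_auc()` with exhaustively tested
  trapezoid / step-wise integration rules.
* **Interpretation** — `integrated_gradients()`, `select_confident()`
  (true-class probability > 0.7), `extract_hot_spots()` (> 70% of the
  per-sequence max attribution), JASPAR scanning at ≥ 80% of a motif's max
  log-odds (`scan_motif()`), enrichment scores f_IR − f_nonIR with a
  permutation null (`enrichment_scores()`, `enrichment_permutation()`), and
  LR weight ranking (`rank_lr_targets()`, `top_bottom_proteins()`).

## Worked example

The attribution pipeline on data with a known causal motif — one sharp
12 bp motif planted into IR sequences with probability 0.9 and into non-IR
sequences with probability 0.05, scanned against that motif plus nine
decoys:

```r
library(irchrom)
res <- motif_recovery_experiment(n_per_class = 1000, seq_len = 300,
                                 n_motifs = 10, plant_prob_ir = 0.9,
                                 plant_prob_nonir = 0.05, seed = 1)
res$test_auroc
#> [1] 0.9339934
res$causal_rank
#> [1] 1
res$causal_p
#> [1] 0.000999001
head(res$enrichment[, c("motif_id", "f_ir", "f_nonir", "score", "rank")], 3)
#>   motif_id      f_ir f_nonir     score rank
#> 1  SYN0001 0.6052632       0 0.6052632    1
#> 2  SYN0002 0.0000000       0 0.0000000    2
#> 3  SYN0003 0.0000000       0 0.0000000    3
```

Reading: the Basset-style classifier reaches test AUROC 0.93 on held-out
sequences; 61% of the integrated-gradients hot spots in IR sequences carry
the causal motif versus 0% in non-IR hot spots, so the causal motif ranks
first with a permutation p of ~0.001, and no decoy shows any enrichment.

The published dataset arithmetic is a one-liner:

```r
dhs_summary(annotation_ir = 16231, annotation_nonir = 55193,
            rnaseq_new = 4568, rnaseq_relabeled = 126)
#> $total_ir      20925
#> $total_nonir   55067
#> $augmented_ir  41850
#> $augmented_nonir 110134
#> $total_sequences 151984
```

## The analysis workflow

Numbered drivers under `analysis/` run the full study at desk scale and
write tables under `results/`:

| script | what it does |
| --- | --- |
| `01_simulate_data.R` | synthetic genome/annotation (FASTA + BED), JASPAR motif library, targets matrix |
| `02_build_dataset.R` | two-phase labeling, redundancy removal, split, augmentation → `manifest.csv` |
| `03_train_sequence_models.R` | Basset-like / Basenji-like / fine-tuned / frozen comparison → `model_comparison.tsv` |
| `04_targets_models.R` | LR on ALL/TF/HM/ACC target subsets + boosted trees; weight ranking → `lr_target_ranking.tsv` |
| `05_interpretation.R` | IG → hot spots → motif scan → enrichment + permutation → `motif_enrichment.tsv` |

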