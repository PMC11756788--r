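#!/usr/bin/env Rscript
# Stage 2: label DHSs, relabel with RNA-seq retained introns, remove
# redundancy, split, and augment — the full dataset construction procedure at
# synthetic scale, with the bookkeeping table the procedure implies.

suppressMessages(library(irchrom))
seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_ir = 60, n_nonir = 180, seq_len = 600, seed = seed)
ann <- simulate_annotation(cfg)

## phase 1: annotation-based labeling (any overlap counts) -------------------
manifest <- build_dhs_dataset(ann, min_overlap = 1)
n_ir0 <- sum(manifest$label == "IR")
message(sprintf("annotation phase: %d IR / %d non-IR DHSs",
                n_ir0, sum(manifest$label == "nonIR")))

## phase 2: RNA-seq relabeling (>= 500 bp overlap) ---------------------------
# synthetic RNA-seq retained introns: recover a few negatives' introns
neg <- manifest[manifest$label == "nonIR", ][1:8, ]
rnaseq <- data.frame(chrom = neg$chrom, start = pmax(0, neg$start - 50),
                     end = neg$end + 50)
out <- relabel_with_rnaseq(manifest, rnaseq, min_overlap = 500)
manifest <- out$dataset
message(sprintf("RNA-seq phase: %d relabeled, %d added",
                out$summary$n_relabeled, out$summary$n_added))

summ <- dhs_summary(annotation_ir = n_ir0,
                    annotation_nonir = nrow(manifest) - n_ir0,
                    rnaseq_new = out$summary$n_added,
                    rnaseq_relabeled = out$summary$n_relabeled)
message(sprintf("totals: %d IR + %d non-IR events; %d sequences after augmentation",
                summ$total_ir, summ$total_nonir, summ$total_sequences))

## redundancy removal + cluster-aware split ----------------------------------
cl <- reduce_redundancy(manifest$seq, threshold = 0.8)
manifest$split <- split_dataset(nrow(manifest), cl, split_config(seed = seed))
message(sprintf("split sizes: %s (on %d clusters)",
                paste(names(table(manifest$split)), table(manifest$split),
                      collapse = " ", sep = "="),
                length(unique(cl))))

## reverse-complement augmentation (training partition) ----------------------
train_aug <- augment_reverse_complement(manifest[manifest$split == "train", ])
message(sprintf("training sequences after augmentation: %d", nrow(train_aug)))

write.csv(manifest[, c("id", "chrom", "start", "end", "strand", "label",
                       "source", "split")],
          "results/manifest.csv", row.names = FALSE, quote = FALSE)
message("wrote results/manifest.csv")
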