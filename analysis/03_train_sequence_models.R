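#!/usr/bin/env Rscript
# Stage 3: train and compare the sequence classifiers on motif-planted DHS
# sequences: the Basset-style CNN, the Basenji-style dilated CNN, the
# fine-tuned backbone (miniature embedder + fine-tuning block with attention
# pooling), and a frozen-backbone variant that freezes the already-trained
# embedder and retrains a fresh head (the transfer-learning ablation).
#
# Desk-scale study conditions: 2 x 1000 sequences of 120 bp, causal motif
# planted at 0.9 / 0.05, reverse-complement augmentation of the training
# partition; training = BCE + AdamW + warmup/cosine + early stopping, with
# seeded restarts guarding against dead initialisations.

suppressMessages(library(irchrom))
seed <- 1L
L <- 120L
dir.create("results", showWarnings = FALSE)

pwms <- simulate_pwm_library(10, width = 12, seed = derive_seed(seed, 301L))
causal <- names(pwms)[1]
sim <- sim_config(1000, 1000, seq_len = L, motif_library = causal,
                  plant_prob_ir = 0.9, plant_prob_nonir = 0.05,
                  seed = derive_seed(seed, 303L))
pl <- plant_motif_sequences(sim, pwms[causal])
y <- as.integer(pl$labels == "IR")
split <- split_dataset(length(y), seq_along(y),
                       split_config(seed = derive_seed(seed, 305L)))
x <- one_hot_batch(pl$sequences)
tr <- which(split == "train"); va <- which(split == "val")
te <- which(split == "test")
xtr <- x[, , tr]
xa <- array(c(xtr, xtr[4:1, L:1, ]), c(4, L, 2 * length(tr)))
train_set <- list(x = xa, y = rep(y[tr], 2))
val_set <- list(x = x[, , va], y = y[va])
tcfg <- train_config(max_epochs = 15, patience = 5, lr = 0.05,
                     batch_size = 64)
head_cfg <- finetune_head_config(conv_channels = 48, dense_units = 32)

builders <- list(
  basset = function(s) basset_like(input_len = L, pools = c(3, 5, 4), seed = s),
  basenji = function(s) basenji_like(input_len = L, n_pooled = 2, seed = s),
  finetuned = function(s) finetune_head(
    mini_backbone(input_len = L, pools = c(4, 5), seed = s),
    head_cfg, seed = s + 1L))

rows <- list()
fits <- list()
for (nm in names(builders)) {
  t0 <- Sys.time()
  r <- fit_with_restarts(builders[[nm]], train_set, val_set, tcfg,
                         seed = derive_seed(seed, 330L + length(rows)))
  sm <- score_summary(nn_predict(r$model, x[, , te]), y[te])
  rows[[nm]] <- data.frame(
    model = nm, n_params = r$model$meta$n_params,
    epochs = nrow(r$history), attempts = r$attempts,
    test_auroc = sm$auroc, test_auprc = sm$auprc,
    minutes = round(as.numeric(difftime(Sys.time(), t0, units = "mins")), 2))
  fits[[nm]] <- r
  message(sprintf("%-16s auroc %.3f  auprc %.3f  (%d epochs, %d attempt(s), %.1f min)",
                  nm, sm$auroc, sm$auprc, nrow(r$history), r$attempts,
                  rows[[nm]]$minutes))
}

## frozen-backbone transfer: freeze the trained embedder, retrain the head
nb <- fits$finetuned$model$meta$n_backbone_layers
trained_backbone <- nn_model(fits$finetuned$model$layers[seq_len(nb)],
                             c(4L, L))
t0 <- Sys.time()
frozen <- finetune_head(trained_backbone, head_cfg, frozen = TRUE,
                        seed = derive_seed(seed, 340L))
r <- fit(frozen, train_set, val_set, tcfg)
sm <- score_summary(nn_predict(r$model, x[, , te]), y[te])
rows$finetuned_frozen <- data.frame(
  model = "finetuned_frozen", n_params = frozen$meta$n_params,
  epochs = nrow(r$history), attempts = 1L,
  test_auroc = sm$auroc, test_auprc = sm$auprc,
  minutes = round(as.numeric(difftime(Sys.time(), t0, units = "mins")), 2))
message(sprintf("%-16s auroc %.3f  auprc %.3f  (%d epochs, %.1f min)",
                "finetuned_frozen", sm$auroc, sm$auprc, nrow(r$history),
                rows$finetuned_frozen$minutes))

tab <- do.call(rbind, rows)
write.table(tab, "results/model_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("wrote results/model_comparison.tsv")
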