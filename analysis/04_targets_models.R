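#!/usr/bin/env Rscript
# Stage 4: interpretable classifiers on the chromatin-targets matrix.
# Fits logistic regression on ALL / TF / HM / ACC target subsets and a
# gradient-boosted tree model, checks recovery of the ground-truth active
# targets, and writes the signed-weight ranking that the interpretation
# stage reads.

suppressMessages(library(irchrom))
seed <- 1L
dir.create("results", showWarnings = FALSE)

st <- simulate_targets(target_sim_config(
  n_samples = 2000, n_targets = 50, n_active = 5, weight_scale = 3,
  seed = derive_seed(seed, 509L)))
n <- nrow(st$targets)
te <- with_seed(derive_seed(seed, 521L), sample.int(n, 400))
Xtr <- st$targets[-te, ]; ytr <- st$labels[-te]
Xte <- st$targets[te, ];  yte <- st$labels[te]

rows <- list()
for (g in c("ALL", "TF", "HM", "ACC")) {
  sub <- subset_targets(Xtr, st$target_meta, g)
  lrm <- logistic_targets_model(sub$targets, ytr, sub$target_meta,
                                seed = derive_seed(seed, 523L))
  p <- predict(lrm, subset_targets(Xte, st$target_meta, g)$targets)
  sm <- score_summary(p, yte)
  rows[[g]] <- data.frame(model = paste0("LR_", g),
                          n_targets = length(lrm$w),
                          test_auroc = sm$auroc, test_auprc = sm$auprc)
  message(sprintf("LR on %-3s (%2d targets): auroc %.3f  auprc %.3f",
                  g, length(lrm$w), sm$auroc, sm$auprc))
  if (g == "ALL") {
    ranking <- rank_lr_targets(lrm)
    write.table(ranking, "results/lr_target_ranking.tsv", sep = "\t",
                quote = FALSE, row.names = FALSE)
    act <- which(st$true_weights != 0)
    hit <- length(intersect(order(-abs(lrm$w))[1:5], act))
    message(sprintf("ground-truth recovery: %d/5 active targets in top-5 |weight|", hit))
    both <- top_bottom_proteins(ranking, k = 10)
    message(sprintf("proteins in both top-10 and bottom-10: %d", length(both)))
  }
}

gb <- gbdt_targets_model(Xtr, ytr, st$target_meta,
                         gbdt_config(n_estimators = 300,
                                     seed = derive_seed(seed, 525L)))
sm <- score_summary(predict(gb, Xte), yte)
rows$GBDT <- data.frame(model = "GBDT_ALL", n_targets = ncol(Xtr),
                        test_auroc = sm$auroc, test_auprc = sm$auprc)
message(sprintf("GBDT on ALL: auroc %.3f  auprc %.3f", sm$auroc, sm$auprc))
imp <- sort(gb$importance, decreasing = TRUE)
write.table(data.frame(target = names(imp), gain = unname(imp)),
            "results/gbdt_importance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(do.call(rbind, rows), "results/targets_model_comparison.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/targets_model_comparison.tsv, lr_target_ranking.tsv, gbdt_importance.tsv")
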