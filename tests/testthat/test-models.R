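test_that("sequence classifiers output probabilities deterministically", {
  set.seed(191)
  x <- array(runif(4 * 150 * 6), c(4, 150, 6))
  for (m in list(basset_like(input_len = 150, seed = 1),
                 basenji_like(input_len = 120, n_pooled = 2, seed = 1))) {
    xb <- if (m$input_shape[2] == 150) x else x[, 1:120, , drop = FALSE]
    p <- nn_predict(m, xb)
    expect_length(p, 6)
    expect_true(all(p > 0 & p < 1))
    expect_identical(p, nn_predict(m, xb))
    expect_gt(m$meta$n_params, 0)
  }
  # same seed, same architecture -> identical weights
  expect_identical(nn_get_params(basset_like(input_len = 150, seed = 7)),
                   nn_get_params(basset_like(input_len = 150, seed = 7)))
})

test_that("basset-like model separates motif-planted classes", {
  pw <- simulate_pwm_library(1, seed = 5)
  sc <- sim_config(300, 300, seq_len = 150, motif_library = names(pw),
                   plant_prob_ir = 1, plant_prob_nonir = 0, seed = 9)
  pl <- plant_motif_sequences(sc, pw)
  x <- one_hot_batch(pl$sequences)
  y <- as.integer(pl$labels == "IR")
  idx <- with_seed(3, sample(600))
  tr <- idx[1:440]; va <- idx[441:520]; te <- idx[521:600]
  xtr <- x[, , tr]
  xa <- array(c(xtr, xtr[4:1, 150:1, ]), c(4, 150, 880))  # revcomp augment
  m <- basset_like(input_len = 150, seed = 2)
  r <- fit(m, list(x = xa, y = rep(y[tr], 2)),
           list(x = x[, , va], y = y[va]),
           train_config(max_epochs = 12, patience = 4, lr = 0.05,
                        batch_size = 64, seed = 4))
  expect_gt(score_summary(nn_predict(r$model, x[, , te]), y[te])$auroc, 0.95)
})

test_that("basenji-like model separates motif-planted classes", {
  pw <- simulate_pwm_library(1, seed = 5)
  sc <- sim_config(300, 300, seq_len = 120, motif_library = names(pw),
                   plant_prob_ir = 1, plant_prob_nonir = 0, seed = 9)
  pl <- plant_motif_sequences(sc, pw)
  x <- one_hot_batch(pl$sequences)
  y <- as.integer(pl$labels == "IR")
  idx <- with_seed(3, sample(600))
  tr <- idx[1:440]; va <- idx[441:520]; te <- idx[521:600]
  xtr <- x[, , tr]
  xa <- array(c(xtr, xtr[4:1, 120:1, ]), c(4, 120, 880))
  m <- basenji_like(input_len = 120, n_pooled = 2, seed = 2)
  r <- fit(m, list(x = xa, y = rep(y[tr], 2)),
           list(x = x[, , va], y = y[va]),
           train_config(max_epochs = 18, patience = 6, lr = 0.05,
                        batch_size = 64, seed = 4))
  expect_gt(score_summary(nn_predict(r$model, x[, , te]), y[te])$auroc, 0.95)
})

test_that("attention pooling weights are a distribution and reduce to mean pooling", {
  set.seed(201)
  lay <- with_seed(3, layer_attention_pool(5))
  x <- array(runif(5 * 7 * 4), c(5, 7, 4))
  fw <- irchrom:::attn_forward(lay, x)
  expect_equal(unname(colSums(fw$cache$a)), rep(1, 4))
  # features constant across positions: attention output equals the mean
  xc <- array(rep(runif(5 * 4), each = 1), c(5, 1, 4))[, rep(1, 7), , drop = FALSE]
  fw2 <- irchrom:::attn_forward(lay, xc)
  mp <- irchrom:::meanpool_forward(layer_mean_pool(), xc)
  expect_equal(fw2$out, mp$out)
})

test_that("finetune head modes and the freeze contract behave as specified", {
  bb <- mini_backbone(input_len = 40, pools = c(2, 2), seed = 6)
  expect_true(check_backbone(bb))
  m_block <- finetune_head(bb, finetune_head_config(conv_channels = 8,
                                                    dense_units = 4), seed = 2)
  m_repl <- finetune_head(bb, mode = "replace", seed = 2)
  x <- array(runif(4 * 40 * 3), c(4, 40, 3))
  expect_true(all(nn_predict(m_block, x) > 0 & nn_predict(m_block, x) < 1))
  expect_true(all(nn_predict(m_repl, x) > 0 & nn_predict(m_repl, x) < 1))
  # frozen backbone: parameters bit-identical before and after training
  m_fr <- finetune_head(bb, finetune_head_config(conv_channels = 8,
                                                 dense_units = 4),
                        frozen = TRUE, seed = 2)
  nb <- m_fr$meta$n_backbone_layers
  before <- nn_get_params(m_fr)[seq_len(nb)]
  y <- c(1, 0, 1)
  r <- fit(m_fr, list(x = x, y = y), list(x = x, y = y),
           train_config(max_epochs = 3, patience = 3, lr = 0.05,
                        batch_size = 2, seed = 8))
  after <- nn_get_params(r$model)[seq_len(nb)]
  expect_identical(before, after)
  # and the head did move
  expect_false(identical(nn_get_params(m_fr)[-seq_len(nb)],
                         nn_get_params(r$model)[-seq_len(nb)]))
  # a flat-vector model is not a valid backbone
  lrm <- nn_model(list(layer_dense(5, 1), layer_sigmoid()), 5)
  expect_error(check_backbone(lrm), "rank")
})

test_that("logistic targets model recovers the active targets and their signs", {
  st <- simulate_targets(target_sim_config(2000, 50, 5, weight_scale = 3,
                                           seed = 7))
  lr <- logistic_targets_model(st$targets, st$labels, st$target_meta, seed = 7)
  act <- which(st$true_weights != 0)
  top5 <- order(-abs(lr$w))[1:5]
  expect_gte(length(intersect(top5, act)), 4)
  # sign recovery for every active weight with |w_true| >= 2
  expect_identical(unname(sign(lr$w[act])), unname(sign(st$true_weights[act])))
  expect_error(logistic_targets_model(st$targets, rep(1, 2000)), "constant")
})

test_that("logistic weights agree with an independent penalised fit", {
  st <- simulate_targets(target_sim_config(1500, 20, 3, weight_scale = 3,
                                           seed = 23))
  lr <- logistic_targets_model(st$targets, st$labels, seed = 23)
  gfit <- glmnet::glmnet(st$targets, st$labels, family = "binomial",
                         alpha = 0, lambda = 1e-4)
  gw <- as.numeric(gfit$beta)
  act <- which(st$true_weights != 0)
  expect_identical(unname(sign(lr$w[act])), sign(gw[act]))
  expect_setequal(order(-abs(lr$w))[1:3], order(-abs(gw))[1:3])
})

test_that("zero weights give probability one half; null features shrink", {
  obj <- structure(list(w = rep(0, 4), b = 0), class = "lr_targets")
  expect_equal(unname(predict(obj, matrix(runif(8), 2, 4))), c(0.5, 0.5))
  st <- simulate_targets(target_sim_config(800, 6, 2, weight_scale = 4,
                                           seed = 29))
  X <- cbind(st$targets, zero = 0)
  lr <- logistic_targets_model(X, st$labels, seed = 29)
  expect_lt(abs(lr$w[["zero"]]), min(abs(lr$w[which(st$true_weights != 0)])))
})

test_that("subset_targets partitions columns by group and preserves order", {
  st <- simulate_targets(target_sim_config(10, 9, 0, seed = 31))
  all_s <- subset_targets(st$targets, st$target_meta, "ALL")
  expect_identical(all_s$targets, st$targets)
  widths <- vapply(c("TF", "HM", "ACC"), function(g) {
    ncol(subset_targets(st$targets, st$target_meta, g)$targets)
  }, integer(1))
  expect_identical(sum(widths), ncol(st$targets))
  tf <- subset_targets(st$targets, st$target_meta, "TF")
  expect_identical(colnames(tf$targets),
                   st$target_meta$target[st$target_meta$group == "TF"])
  bad_meta <- st$target_meta
  bad_meta$group[1] <- "XX"
  expect_error(subset_targets(st$targets, bad_meta), "unknown")
})

test_that("boosted trees rank active targets highly and predict probabilities", {
  st <- simulate_targets(target_sim_config(1200, 40, 4, weight_scale = 4,
                                           seed = 37))
  gb <- gbdt_targets_model(st$targets, st$labels, st$target_meta,
                           gbdt_config(n_estimators = 80, seed = 37))
  act <- which(st$true_weights != 0)
  decile <- order(-gb$importance)[1:4]
  expect_gte(length(intersect(decile, act)), 3)
  p <- predict(gb, st$targets)
  expect_true(all(p >= 0 & p <= 1))
  # permuting an inactive feature barely moves held-out discrimination
  inert <- setdiff(seq_len(40), act)[1]
  Xp <- st$targets
  Xp[, inert] <- with_seed(1, sample(Xp[, inert]))
  a0 <- roc_auc(predict(gb, st$targets), st$labels)$auc
  a1 <- roc_auc(predict(gb, Xp), st$labels)$auc
  expect_lt(abs(a0 - a1), 0.02)
})
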