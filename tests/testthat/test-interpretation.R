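test_that("integrated gradients vanish at the baseline and are exact for linear models", {
  # linear scalar model: f(x) = w.x + b, so IG = w * (x - baseline) exactly
  lin <- with_seed(8, nn_model(list(layer_flatten(), layer_dense(24, 1)),
                               c(4, 6)))
  x <- one_hot("ACGTAC")
  for (steps in c(1, 7, 50)) {
    ig <- integrated_gradients(lin, x, steps = steps)
    w <- matrix(lin$layers[[2]]$params$W, 4, 6)
    expect_equal(ig$values, w * x, tolerance = 1e-10)
  }
  ig0 <- integrated_gradients(lin, x, baseline = x)
  expect_true(all(ig0$values == 0))
  expect_error(integrated_gradients(lin, x, baseline = matrix(0, 4, 5)),
               "shape")
})

test_that("IG completeness error shrinks with the number of steps", {
  set.seed(211)
  cnn <- with_seed(3, nn_model(list(
    layer_conv1d(4, 6, 5), layer_relu(), layer_maxpool(4),
    layer_conv1d(6, 4, 3), layer_gelu(), layer_maxpool(5),
    layer_flatten(), layer_dense(4, 1), layer_sigmoid()), c(4, 20)))
  x <- one_hot(random_dna(1, 20))
  gaps <- vapply(c(10, 50, 200), function(s) {
    abs(integrated_gradients(cnn, x, steps = s)$completeness_gap)
  }, numeric(1))
  expect_lt(gaps[3], gaps[1] + 1e-12)
  span <- abs(nn_predict(cnn, x) -
              nn_predict(cnn, x * 0))
  expect_lt(gaps[3], 0.01 * span + 1e-10)
  # batch version agrees with the single-sequence version
  xs <- array(c(x, one_hot(random_dna(1, 20))), c(4, 20, 2))
  igb <- integrated_gradients_batch(cnn, xs, steps = 25, chunk = 2)
  ig1 <- integrated_gradients(cnn, xs[, , 1], steps = 25)
  expect_equal(igb[, , 1], ig1$values, tolerance = 1e-10)
})

test_that("confident-sequence selection applies the rule symmetrically", {
  probs <- c(0.71, 0.69, 0.2, 0.31, 0.95)
  labels <- c("IR", "IR", "nonIR", "nonIR", "nonIR")
  keep <- select_confident(probs, labels, 0.7)
  expect_identical(as.vector(keep), c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_identical(attr(keep, "n_ir_kept"), 1L)
  expect_identical(attr(keep, "n_nonir_kept"), 1L)
  # a perfect model keeps everything
  expect_true(all(select_confident(c(0.99, 0.01), c(1, 0), 0.7)))
})

test_that("hot-spot extraction follows the fraction-of-max rule, signs preserved", {
  onehot <- one_hot("AAA")
  values <- rbind(c(1.0, 0.5, 0.8), matrix(0, 3, 3))
  hs <- extract_hot_spots(values, onehot, frac = 0.7)
  expect_identical(hs$position, c(0L, 2L))
  # all equal and positive: every position is a hot spot
  ve <- rbind(rep(0.4, 3), matrix(0, 3, 3))
  expect_identical(nrow(extract_hot_spots(ve, onehot, 0.7)), 3L)
  # all non-positive: no scalar strictly exceeds frac * max
  vn <- rbind(c(-1, -0.5, -0.8), matrix(0, 3, 3))
  expect_identical(nrow(extract_hot_spots(vn, onehot, 0.7)), 0L)
  # invariant to positive rescaling
  hs2 <- extract_hot_spots(values * 37, onehot, frac = 0.7)
  expect_identical(hs$position, hs2$position)
  # all-N sequence has no observed-base signal
  expect_identical(nrow(extract_hot_spots(values, one_hot("NNN"), 0.7)), 0L)
  # magnitude mode recovers strong negative positions (|-1| and |-0.8|)
  expect_identical(nrow(extract_hot_spots(vn, onehot, 0.7, abs_attr = TRUE)), 2L)
})

test_that("motif window scanning matches exhaustive enumeration for k = 2", {
  p <- pwm("TOY", "toy", matrix(c(8, 1, 1, 1,
                                  1, 1, 8, 1), 4, 2), pseudocount = 0.01)
  dinucs <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T")),
                  1, paste0, collapse = "")
  for (d in dinucs) {
    # brute force: score both the window and its reverse complement directly
    b <- c(A = 1, C = 2, G = 3, T = 4)
    sc_fwd <- sum(log(p$probs[cbind(b[strsplit(d, "")[[1]]], 1:2)] / 0.25))
    rcd <- revcomp(d)
    sc_rev <- sum(log(p$probs[cbind(b[strsplit(rcd, "")[[1]]], 1:2)] / 0.25))
    want <- max(sc_fwd, sc_rev) >= 0.8 * p$max_score
    expect_identical(scan_motif(d, 0, p, 0.8), want, info = d)
    expect_identical(scan_motif(d, 1, p, 0.8), want, info = d)
  }
})

test_that("consensus windows reach the maximum score on either strand", {
  p <- consensus_pwm("ACGGTA")
  s <- paste0("TTTT", "ACGGTA", "TTTT")
  sc <- scan_sequence(s, p)
  expect_equal(max(sc$fwd), p$max_score)
  expect_true(scan_motif(s, 6, p, 1))
  # the reverse complement of the sequence matches through the other strand
  expect_true(scan_motif(revcomp(s), 6, p, 1))
  # a center with no covering window inside bounds cannot match
  expect_false(scan_motif("ACG", 2, consensus_pwm("ACGGTA"), 0.5))
})

test_that("enrichment scores are the difference of class match fractions", {
  # 10 IR hot spots of which 3 match; 20 non-IR of which 1 matches
  p <- consensus_pwm("ACGGTACG")
  match_seq <- paste0(strrep("T", 4), "ACGGTACG", strrep("T", 4))
  bg_seq <- strrep("T", 16)
  seqs <- c(rep(match_seq, 4), rep(bg_seq, 26))
  names(seqs) <- sprintf("s%02d", 1:30)
  hotspots <- data.frame(
    seq_id = names(seqs),
    position = 8L,
    class = rep(c("IR", "nonIR"), c(10, 20)))
  # arrange: IR hot spots on 3 matching seqs, non-IR on 1
  hotspots$seq_id <- c(names(seqs)[1:3], names(seqs)[5:11],
                       names(seqs)[4], names(seqs)[12:30])
  enr <- enrichment_scores(hotspots, seqs, list(M1 = p))
  expect_equal(enr$f_ir, 0.3)
  expect_equal(enr$f_nonir, 0.05)
  expect_equal(enr$score, 0.25)
  # a motif matching every hot spot scores zero
  hot_all <- data.frame(seq_id = rep(names(seqs)[1], 6), position = 8L,
                        class = rep(c("IR", "nonIR"), 3))
  enr2 <- enrichment_scores(hot_all, seqs, list(M1 = p))
  expect_equal(enr2$score, 0)
  expect_error(enrichment_scores(hotspots[hotspots$class == "IR", ], seqs,
                                 list(M1 = p)), "both classes")
})

test_that("permuting hot-spot labels centers enrichment at zero", {
  set.seed(221)
  mm <- matrix(runif(300) < 0.3, 100, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  is_ir <- rep(c(TRUE, FALSE), 50)
  perm <- enrichment_permutation(mm, is_ir, n_perm = 500, seed = 3)
  ps <- attr(perm, "perm_scores")
  expect_lt(max(abs(rowMeans(ps))), 0.03)
  expect_true(all(perm$p_value > 0 & perm$p_value <= 1))
})

test_that("target ranking by logistic weight handles metadata and degeneracy", {
  st <- simulate_targets(target_sim_config(1200, 12, 3, weight_scale = 4,
                                           seed = 43))
  lr <- logistic_targets_model(st$targets, st$labels, st$target_meta, seed = 43)
  rk <- rank_lr_targets(lr)
  expect_identical(nrow(rk), 12L)
  expect_true(all(diff(rk$weight) <= 0))
  # strongest positive ground-truth target sits near the top
  top_true <- st$target_meta$target[which.max(st$true_weights)]
  expect_lte(rk$rank[rk$target == top_true], 2L)
  # a protein assayed as two targets occupies two ranks
  dup <- names(which(table(rk$protein) >= 2))[1]
  expect_gte(length(unique(rk$rank[rk$protein == dup])), 2L)
  # top/bottom intersection is well-defined
  tb <- top_bottom_proteins(rk, k = 6)
  expect_true(is.character(tb))
  # degenerate all-zero weights are flagged
  obj <- structure(list(w = setNames(rep(0, 3), c("a", "b", "c")),
                        b = 0, target_meta = NULL), class = "lr_targets")
  expect_warning(rk0 <- rank_lr_targets(obj), "degenerate")
  expect_true(attr(rk0, "degenerate"))
  expect_error(rank_lr_targets(lr, st$target_meta[1:3, ]), "width")
})

test_that("JASPAR round trip preserves motif content", {
  pwms <- simulate_pwm_library(3, width = c(6, 8, 10), seed = 47)
  f <- tempfile(fileext = ".pfm")
  write_jaspar(pwms, f)
  back <- read_jaspar(f)
  expect_identical(names(back), names(pwms))
  for (m in names(pwms)) {
    expect_identical(back[[m]]$width, pwms[[m]]$width)
    expect_lt(max(abs(back[[m]]$probs - pwms[[m]]$probs)), 0.01)
    # consensus preserved exactly
    expect_identical(apply(back[[m]]$probs, 2, which.max),
                     apply(pwms[[m]]$probs, 2, which.max))
  }
})
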