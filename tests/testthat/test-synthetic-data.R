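test_that("simulate_annotation yields the configured interval structure", {
  cfg <- sim_config(n_ir = 10, n_nonir = 30, seq_len = 600, seed = 1)
  ann <- simulate_annotation(cfg)
  expect_length(ann$dhs, 40)
  expect_true(all(GenomicRanges::width(ann$dhs) == 600))
  expect_length(ann$retained_introns, 10)
  expect_equal(ann$ir_fraction, 0.25)
  # every DHS lies inside a chromosome of the genome
  expect_true(all(GenomicRanges::end(ann$dhs) <= nchar(ann$genome["chrS"])))
  # labels recovered by the overlap rule match the generating classes
  expect_equal(label_dhs(ann$dhs, ann$retained_introns), ann$dhs$class)
})

test_that("annotation generation is deterministic and writes byte-identical files", {
  cfg <- sim_config(n_ir = 4, n_nonir = 6, seq_len = 200, seed = 42)
  d1 <- file.path(tempdir(), "ann_a")
  d2 <- file.path(tempdir(), "ann_b")
  write_annotation(simulate_annotation(cfg), d1)
  write_annotation(simulate_annotation(cfg), d2)
  for (f in c("genome.fa", "retained_introns.bed", "dhs.bed")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("degenerate and invalid annotation configs are handled", {
  ann <- simulate_annotation(sim_config(n_ir = 0, n_nonir = 12, seed = 3))
  expect_length(ann$retained_introns, 0)
  expect_true(all(label_dhs(ann$dhs, ann$retained_introns) == "nonIR"))
  expect_error(simulate_annotation(sim_config(5, 5, seq_len = 600, seed = 1),
                                   intron_len = 500),
               "reject")
})

test_that("motif planting follows class-conditional probabilities", {
  pwms <- simulate_pwm_library(2, width = 8, seed = 7)
  cfg <- sim_config(n_ir = 50, n_nonir = 50, seq_len = 120,
                    motif_library = names(pwms),
                    plant_prob_ir = 1, plant_prob_nonir = 0, seed = 11)
  pl <- plant_motif_sequences(cfg, pwms)
  ir_ids <- names(pl$sequences)[pl$labels == "IR"]
  for (m in names(pwms)) {
    planted_in <- pl$plant_log$seq_id[pl$plant_log$motif_id == m]
    expect_setequal(planted_in, ir_ids)
  }
  # planted instances are on record at the logged offsets: the logged window
  # scores at least as high as expected for a draw from the PWM
  r1 <- pl$plant_log[1, ]
  k <- pwms[[r1$motif_id]]$width
  expect_identical(nchar(substr(pl$sequences[[r1$seq_id]],
                                r1$offset + 1, r1$offset + k)), k)
})

test_that("observed planting fraction falls in the binomial 99% CI", {
  pwms <- simulate_pwm_library(1, width = 8, seed = 2)
  n_ir <- 1000
  cfg <- sim_config(n_ir = n_ir, n_nonir = 10, seq_len = 80,
                    motif_library = names(pwms),
                    plant_prob_ir = 0.8, plant_prob_nonir = 0, seed = 5)
  pl <- plant_motif_sequences(cfg, pwms)
  ir_ids <- names(pl$sequences)[pl$labels == "IR"]
  n_planted <- sum(pl$plant_log$seq_id %in% ir_ids)
  ci <- qbinom(c(0.005, 0.995), n_ir, 0.8)
  expect_gte(n_planted, ci[1])
  expect_lte(n_planted, ci[2])
})

test_that("planting without motifs gives pure background and empty log", {
  cfg <- sim_config(n_ir = 5, n_nonir = 5, seq_len = 50, seed = 8)
  pl <- plant_motif_sequences(cfg, list())
  expect_identical(nrow(pl$plant_log), 0L)
  expect_true(all(nchar(pl$sequences) == 50))
})

test_that("planting is deterministic and motifs too long are rejected", {
  pwms <- simulate_pwm_library(1, width = 30, seed = 1)
  cfg <- sim_config(2, 2, seq_len = 20, motif_library = names(pwms),
                    plant_prob_ir = 1, seed = 1)
  expect_error(plant_motif_sequences(cfg, pwms), "longer")
  pwms2 <- simulate_pwm_library(2, width = 6, seed = 3)
  cfg2 <- sim_config(10, 10, seq_len = 60, motif_library = names(pwms2),
                     plant_prob_ir = 0.5, plant_prob_nonir = 0.5, seed = 9)
  a <- plant_motif_sequences(cfg2, pwms2)
  b <- plant_motif_sequences(cfg2, pwms2)
  expect_identical(a, b)
})

test_that("simulate_targets draws labels from the stated logistic model", {
  # calibration: empirical label frequency tracks sigmoid(w.x + b)
  cfg <- target_sim_config(n_samples = 6000, n_targets = 8, n_active = 4,
                           weight_scale = 4, noise_sd = 0, seed = 13)
  st <- simulate_targets(cfg)
  eta <- drop(st$targets %*% st$true_weights) + st$bias
  p <- 1 / (1 + exp(-eta))
  bins <- cut(p, breaks = seq(0, 1, 0.2), include.lowest = TRUE)
  for (b in levels(bins)) {
    i <- bins == b
    if (sum(i) < 100) next
    se <- sqrt(mean(p[i]) * (1 - mean(p[i])) / sum(i))
    expect_lt(abs(mean(st$labels[i]) - mean(p[i])), 5 * se + 0.01)
  }
  expect_identical(sum(st$true_weights != 0), 4L)
  expect_true(all(st$targets >= 0 & st$targets <= 1))
  expect_setequal(unique(st$target_meta$group), c("TF", "HM", "ACC"))
})

test_that("null targets carry no label information", {
  cfg <- target_sim_config(n_samples = 1200, n_targets = 10, n_active = 0,
                           seed = 17)
  st <- simulate_targets(cfg)
  half <- seq_len(600)
  fitg <- suppressWarnings(glm(y ~ ., family = binomial(),
             data = data.frame(y = st$labels[half], st$targets[half, ])))
  pred <- predict(fitg, newdata = data.frame(st$targets[-half, ]))
  expect_lt(abs(roc_auc(pred, st$labels[-half])$auc - 0.5), 0.08)
})

test_that("explicit weights give the closed-form label probability", {
  w <- c(5, -5, rep(0, 4))
  cfg <- target_sim_config(n_samples = 10, n_targets = 6, n_active = 2, seed = 19)
  st <- simulate_targets(cfg, weights = w)
  expect_identical(st$true_weights, w)
  expect_identical(st$bias, 0)  # -sum(w)/2
  # a sample at x = (1, 0, ...) has label-1 probability sigmoid(5 + b)
  expect_equal(sigmoid(sum(w * c(1, rep(0, 5))) + st$bias), sigmoid(5))
})
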