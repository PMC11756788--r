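#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emits a small synthetic genome with retained-intron annotations and DHS
# intervals (FASTA + BED), a library of synthetic TF motifs in JASPAR PFM
# format, and a chromatin-targets matrix drawn from a known sparse logistic
# model. Everything downstream (labeling, training, interpretation) runs off
# these files plus the in-memory generators, so every stage has known ground
# truth.

suppressMessages(library(irchrom))
seed <- 1L
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

## annotation + DHS intervals -----------------------------------------------
cfg <- sim_config(n_ir = 60, n_nonir = 180, seq_len = 600, seed = seed)
ann <- simulate_annotation(cfg)
paths <- write_annotation(ann, "results/data")
message(sprintf("genome: %d bp on %d chromosome(s); %d DHSs (%.0f%% in retained introns)",
                sum(nchar(ann$genome)), length(ann$genome), length(ann$dhs),
                100 * ann$ir_fraction))

## motif library -------------------------------------------------------------
pwms <- simulate_pwm_library(10, width = 12, seed = derive_seed(seed, 301L))
write_jaspar(pwms, "results/data/motifs_synthetic.pfm")
message("wrote 10 synthetic JASPAR motifs (SYN0001 is used as the causal motif downstream)")

## chromatin-targets matrix ---------------------------------------------------
st <- simulate_targets(target_sim_config(
  n_samples = 2000, n_targets = 50, n_active = 5, weight_scale = 3,
  seed = derive_seed(seed, 509L)))
write.table(cbind(st$target_meta, true_weight = st$true_weights),
            "results/data/target_meta.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample = seq_along(st$labels), label = st$labels),
            "results/data/target_labels.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("targets matrix: %d x %d, %d active targets, prevalence %.2f",
                nrow(st$targets), ncol(st$targets), sum(st$true_weights != 0),
                mean(st$labels)))
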