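#' Configuration for the synthetic DHS sequence generator
#'
#' Describes a two-class population of open-chromatin (DHS) sequences in which
#' class membership is driven by planted transcription-factor motifs: each
#' motif in `motif_library` is planted into an IR-class sequence with
#' probability `plant_prob_ir` and into a non-IR sequence with probability
#' `plant_prob_nonir`. Background bases are i.i.d. with GC content
#' `gc_background`. All randomness is fixed by `seed`.
#'
#' @param n_ir,n_nonir number of IR / non-IR class sequences.
#' @param seq_len sequence length in bp (the pipeline's DHS unit is 600 bp).
#' @param motif_library character vector of PWM ids to plant (may be empty).
#' @param plant_prob_ir,plant_prob_nonir per-motif class-conditional planting
#'   probabilities; either scalars or vectors parallel to `motif_library`.
#' @param gc_background background G+C probability.
#' @param seed integer master seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_ir, n_nonir, seq_len = 600L, motif_library = character(),
                       plant_prob_ir = 0, plant_prob_nonir = 0,
                       gc_background = 0.41, seed = 1L) {
  stopifnot(n_ir >= 0, n_nonir >= 0, seq_len >= 1)
  check_prob(plant_prob_ir, "plant_prob_ir")
  check_prob(plant_prob_nonir, "plant_prob_nonir")
  check_prob(gc_background, "gc_background")
  n_m <- length(motif_library)
  structure(list(
    n_ir = as.integer(n_ir), n_nonir = as.integer(n_nonir),
    seq_len = as.integer(seq_len), motif_library = motif_library,
    plant_prob_ir = rep_len(plant_prob_ir, n_m),
    plant_prob_nonir = rep_len(plant_prob_nonir, n_m),
    gc_background = gc_background, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Sample i.i.d. background DNA with a given GC content
#' @noRd
random_background <- function(n, len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

#' Simulate a genome annotation with retained introns and DHS intervals
#'
#' Lays out `n_ir + n_nonir` introns on a single synthetic chromosome,
#' separated by spacer sequence. The first `n_ir` introns are marked as
#' retained; every intron contains exactly one DHS interval of length
#' `cfg$seq_len`, placed uniformly at random inside the intron, so the
#' fraction of DHSs overlapping retained introns equals
#' `n_ir / (n_ir + n_nonir)` by construction and is recorded in the result.
#' Intron order along the chromosome is shuffled (seeded) so class does not
#' correlate with coordinate.
#'
#' @param cfg a [sim_config].
#' @param intron_len intron length in bp; must be at least `cfg$seq_len`.
#' @param spacer_len spacer between introns (and at chromosome ends), bp.
#' @return a `synthetic_annotation` list with elements `genome` (named
#'   character vector of chromosome sequences), `retained_introns`,
#'   `non_ir_introns` and `dhs` (all [GenomicRanges::GRanges], 0-based
#'   half-open when exported as BED), and `ir_fraction`.
#' @export
simulate_annotation <- function(cfg, intron_len = cfg$seq_len + 400L,
                                spacer_len = 200L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (intron_len < cfg$seq_len) {
    stop("`seq_len` exceeds the simulated intron length; reject config", call. = FALSE)
  }
  n <- cfg$n_ir + cfg$n_nonir
  with_seed(derive_seed(cfg$seed, 11L), {
    classes <- sample(rep(c("IR", "nonIR"), c(cfg$n_ir, cfg$n_nonir)))
    glen <- spacer_len + n * (intron_len + spacer_len)
    genome <- random_background(1L, glen, cfg$gc_background)
    names(genome) <- "chrS"
    # 1-based inclusive coordinates internally (GRanges convention)
    istart <- spacer_len + 1L + (seq_len(n) - 1L) * (intron_len + spacer_len)
    introns <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(istart, width = intron_len), strand = "+")
    doff <- floor(stats::runif(n, 0, intron_len - cfg$seq_len + 1))
    dhs <- GenomicRanges::GRanges("chrS",
      IRanges::IRanges(istart + doff, width = cfg$seq_len), strand = "+")
    dhs$name <- sprintf("dhs_%04d", seq_len(n))
    dhs$class <- classes
    structure(list(
      genome = genome,
      retained_introns = introns[classes == "IR"],
      non_ir_introns = introns[classes == "nonIR"],
      dhs = dhs,
      ir_fraction = if (n > 0) cfg$n_ir / n else NA_real_
    ), class = "synthetic_annotation")
  })
}

#' Write a synthetic annotation to FASTA + BED files
#'
#' Emits `genome.fa`, `retained_introns.bed` and `dhs.bed` (BED6, 0-based
#' half-open). Byte-identical output for identical inputs.
#'
#' @param ann a `synthetic_annotation` from [simulate_annotation()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_annotation <- function(ann, dir) {
  stopifnot(inherits(ann, "synthetic_annotation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ann$genome), fa)
  ri <- ann$retained_introns
  ri$name <- sprintf("retained_%04d", seq_along(ri))
  ri$score <- 0L
  bed1 <- file.path(dir, "retained_introns.bed")
  rtracklayer::export(ri, bed1, format = "BED")
  dhs <- ann$dhs
  dhs$score <- 0L
  bed2 <- file.path(dir, "dhs.bed")
  rtracklayer::export(dhs, bed2, format = "BED")
  invisible(c(genome = fa, retained_introns = bed1, dhs = bed2))
}

#' Plant PWM motifs into background sequences, class-conditionally
#'
#' Generates `n_ir` IR-class and `n_nonir` non-IR-class background sequences
#' and, for each sequence and each motif in `cfg$motif_library`, plants one
#' instance (sampled from the PWM, uniformly random non-overlapping offset,
#' random strand) with the class-conditional probability from `cfg`. Planted
#' instances never overlap one another within a sequence, so downstream
#' attribution has unambiguous ground truth.
#'
#' @param cfg a [sim_config].
#' @param pwms named list of [pwm] objects covering `cfg$motif_library`.
#' @return list with `sequences` (named character vector), `labels` (factor
#'   `IR`/`nonIR`), and `plant_log` (data.frame seq_id, motif_id, offset
#'   (0-based), strand).
#' @export
plant_motif_sequences <- function(cfg, pwms) {
  stopifnot(inherits(cfg, "sim_config"))
  use <- cfg$motif_library
  missing <- setdiff(use, names(pwms))
  if (length(missing)) stop("missing PWMs: ", paste(missing, collapse = ", "), call. = FALSE)
  widths <- vapply(pwms[use], `[[`, numeric(1), "width")
  if (length(widths) && max(widths) > cfg$seq_len) {
    stop("a motif is longer than `seq_len`", call. = FALSE)
  }
  n <- cfg$n_ir + cfg$n_nonir
  labels <- factor(rep(c("IR", "nonIR"), c(cfg$n_ir, cfg$n_nonir)),
                   levels = c("IR", "nonIR"))
  with_seed(derive_seed(cfg$seed, 23L), {
    seqs <- random_background(n, cfg$seq_len, cfg$gc_background)
    names(seqs) <- sprintf("seq_%05d", seq_len(n))
    log_rows <- vector("list", n)
    for (i in seq_len(n)) {
      probs <- if (labels[i] == "IR") cfg$plant_prob_ir else cfg$plant_prob_nonir
      occupied <- logical(cfg$seq_len)
      chars <- strsplit(seqs[i], "")[[1]]
      entries <- list()
      for (m in seq_along(use)) {
        if (stats::runif(1) >= probs[m]) next
        k <- pwms[[use[m]]]$width
        ok <- vapply(seq_len(cfg$seq_len - k + 1L), function(s) {
          !any(occupied[s:(s + k - 1L)])
        }, logical(1))
        starts <- which(ok)
        if (!length(starts)) {
          stop("cannot place motif without overlap: planted motifs exceed seq_len",
               call. = FALSE)
        }
        s <- if (length(starts) == 1L) starts else sample(starts, 1L)
        strand <- sample(c("+", "-"), 1L)
        inst <- sample_motif_instance(pwms[[use[m]]])
        if (strand == "-") inst <- revcomp(inst)
        chars[s:(s + k - 1L)] <- strsplit(inst, "")[[1]]
        occupied[s:(s + k - 1L)] <- TRUE
        entries[[length(entries) + 1L]] <- data.frame(
          seq_id = names(seqs)[i], motif_id = use[m],
          offset = s - 1L, strand = strand, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(chars, collapse = "")
      log_rows[[i]] <- if (length(entries)) do.call(rbind, entries) else NULL
    }
    plant_log <- do.call(rbind, log_rows)
    if (is.null(plant_log)) {
      plant_log <- data.frame(seq_id = character(), motif_id = character(),
                              offset = integer(), strand = character(),
                              stringsAsFactors = FALSE)
    }
    list(sequences = seqs, labels = labels, plant_log = plant_log)
  })
}

#' Generate a synthetic library of sharp PWMs
#'
#' Each motif concentrates most probability on one consensus base per column,
#' mimicking informative JASPAR TF motifs; used as causal motifs and decoys in
#' recovery experiments.
#'
#' @param n number of motifs.
#' @param width motif width in bp (scalar or vector of length `n`).
#' @param seed integer seed.
#' @param sharpness consensus-base count weight (larger = more informative);
#'   the default puts ~94% probability on the consensus base per column,
#'   comparable to high-information TF motifs.
#' @return named list of [pwm] objects with ids `SYN0001`, ...
#' @export
simulate_pwm_library <- function(n, width = 12L, seed = 1L, sharpness = 50) {
  width <- rep_len(as.integer(width), n)
  with_seed(derive_seed(seed, 37L), {
    out <- lapply(seq_len(n), function(i) {
      counts <- matrix(1, 4, width[i])
      consensus <- sample.int(4L, width[i], replace = TRUE)
      counts[cbind(consensus, seq_len(width[i]))] <- sharpness
      pwm(sprintf("SYN%04d", i), sprintf("SynTF%d", i), counts)
    })
    names(out) <- vapply(out, `[[`, character(1), "id")
    out
  })
}

#' Configuration for the chromatin-targets simulator
#'
#' @param n_samples,n_targets matrix dimensions.
#' @param n_active number of targets with nonzero ground-truth weight.
#' @param weight_scale magnitude of active weights (signs alternate).
#' @param noise_sd standard deviation of Gaussian logit noise.
#' @param seed integer seed.
#' @return a `target_sim_config` list.
#' @export
target_sim_config <- function(n_samples, n_targets, n_active,
                              weight_scale = 3, noise_sd = 0, seed = 1L) {
  stopifnot(n_active <= n_targets, noise_sd >= 0, n_samples >= 1)
  structure(list(
    n_samples = as.integer(n_samples), n_targets = as.integer(n_targets),
    n_active = as.integer(n_active), weight_scale = weight_scale,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "target_sim_config")
}

#' Simulate a chromatin-targets matrix from a known sparse logistic model
#'
#' Draws target scores uniformly in \[0, 1\], picks `n_active` targets with
#' alternating-sign weights of magnitude `weight_scale`, and samples labels
#' from `Bernoulli(sigmoid(w . x + b + noise))` with the bias centering the
#' logit at zero for an average sample. Per-target metadata assigns each
#' target to a group (TF / HM / ACC) and a protein; some proteins are
#' deliberately assayed as multiple targets, as in real chromatin-profile
#' compendia.
#'
#' @param cfg a [target_sim_config].
#' @param weights optional explicit ground-truth weight vector (overrides the
#'   alternating-sign construction; length `n_targets`).
#' @return list with `targets` (matrix), `target_meta` (data.frame: target,
#'   protein, group), `labels` (0/1), `true_weights`, `bias`.
#' @export
simulate_targets <- function(cfg, weights = NULL) {
  stopifnot(inherits(cfg, "target_sim_config"))
  with_seed(derive_seed(cfg$seed, 41L), {
    X <- matrix(stats::runif(cfg$n_samples * cfg$n_targets),
                cfg$n_samples, cfg$n_targets)
    if (is.null(weights)) {
      w <- numeric(cfg$n_targets)
      if (cfg$n_active > 0) {
        active <- sample.int(cfg$n_targets, cfg$n_active)
        w[active] <- cfg$weight_scale * rep_len(c(1, -1), cfg$n_active)
      }
    } else {
      stopifnot(length(weights) == cfg$n_targets)
      w <- weights
    }
    b <- -sum(w) / 2  # E[x_j] = 1/2, so logits are centered
    eta <- drop(X %*% w) + b +
      if (cfg$noise_sd > 0) stats::rnorm(cfg$n_samples, 0, cfg$noise_sd) else 0
    y <- stats::rbinom(cfg$n_samples, 1L, sigmoid(eta))
    tid <- sprintf("t%04d", seq_len(cfg$n_targets))
    colnames(X) <- tid
    meta <- data.frame(
      target = tid,
      protein = sprintf("PROT%03d", ceiling(seq_len(cfg$n_targets) * 0.7)),
      group = rep_len(c("TF", "HM", "ACC"), cfg$n_targets),
      stringsAsFactors = FALSE
    )
    list(targets = X, target_meta = meta, labels = y, true_weights = w, bias = b)
  })
}
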