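#' Convert a BED-style data.frame to GRanges
#'
#' BED convention throughout: 0-based half-open `[start, end)`. GRanges is
#' 1-based inclusive, so `start` is shifted by one on conversion.
#'
#' @param x a data.frame with columns `chrom`, `start`, `end` and optionally
#'   `strand`, or an existing `GRanges` (returned unchanged).
#' @return a [GenomicRanges::GRanges].
#' @export
bed_to_granges <- function(x) {
  if (methods::is(x, "GRanges")) return(x)
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(GenomicRanges::GRanges())
  if (any(x$start < 0) || any(x$start >= x$end)) {
    stop("malformed interval: require 0 <= start < end", call. = FALSE)
  }
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1L, x$end),
                         strand = strand)
}

#' Label DHS intervals by overlap with retained introns
#'
#' A DHS is labeled `IR` iff its best overlap with any retained intron is at
#' least `min_overlap` bp; the overlap of half-open intervals `[a,b)`, `[c,d)`
#' is `max(0, min(b,d) - max(a,c))`. The annotation phase uses
#' `min_overlap = 1` (any overlap); the RNA-seq phase uses 500 bp.
#'
#' @param dhs DHS intervals (`GRanges` or BED data.frame).
#' @param retained retained-intron intervals (`GRanges` or BED data.frame).
#' @param min_overlap minimum overlap in bp for the IR label.
#' @return character vector of labels (`"IR"`/`"nonIR"`), one per DHS.
#' @export
label_dhs <- function(dhs, retained, min_overlap = 1L) {
  stopifnot(min_overlap >= 1)
  dhs <- bed_to_granges(dhs)
  retained <- bed_to_granges(retained)
  hits <- GenomicRanges::findOverlaps(dhs, retained,
                                      minoverlap = as.integer(min_overlap),
                                      ignore.strand = TRUE)
  labels <- rep("nonIR", length(dhs))
  labels[unique(S4Vectors::queryHits(hits))] <- "IR"
  labels
}

#' Best overlap (bp) of each query interval with a set of subject intervals
#' @noRd
best_overlap <- function(query, subject) {
  hits <- GenomicRanges::findOverlaps(query, subject, ignore.strand = TRUE)
  ov <- rep(0L, length(query))
  if (length(hits)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      query[S4Vectors::queryHits(hits)], subject[S4Vectors::subjectHits(hits)],
      ignore.strand = TRUE))
    agg <- tapply(w, S4Vectors::queryHits(hits), max)
    ov[as.integer(names(agg))] <- as.integer(agg)
  }
  ov
}

#' Relabel and extend a DHS dataset with RNA-seq retained introns
#'
#' Every non-IR sample overlapping an RNA-seq retained intron by at least
#' `min_overlap` bp is flipped to IR (`source = "rnaseq_relabel"`); IR labels
#' are never flipped back, so the IR count is non-decreasing. Candidate new
#' DHSs passing the same rule are appended with `source = "rnaseq_new"`.
#'
#' @param dataset manifest data.frame with columns `id`, `chrom`, `start`,
#'   `end`, `strand`, `label`, `source` (and optionally `seq`).
#' @param rnaseq_retained retained introns called from RNA-seq
#'   (`GRanges`/BED data.frame).
#' @param new_dhs optional data.frame of candidate new DHSs (same interval
#'   columns as `dataset`); rows not passing the overlap rule are dropped.
#' @param min_overlap minimum overlap in bp (default 500).
#' @return list with `dataset` (updated manifest) and `summary`
#'   (`n_relabeled`, `n_added`).
#' @export
relabel_with_rnaseq <- function(dataset, rnaseq_retained, new_dhs = NULL,
                                min_overlap = 500L) {
  gr <- bed_to_granges(dataset)
  rna <- bed_to_granges(rnaseq_retained)
  key <- function(d) paste(d$chrom, d$start, d$end, sep = ":")
  if (!is.null(new_dhs) && nrow(new_dhs) > 0) {
    if (any(key(new_dhs) %in% key(dataset))) {
      stop("duplicate interval between `dataset` and `new_dhs`; deduplicate upstream",
           call. = FALSE)
    }
  }
  flip <- dataset$label == "nonIR" &
    (if (length(rna)) best_overlap(gr, rna) >= min_overlap else FALSE)
  dataset$label[flip] <- "IR"
  dataset$source[flip] <- "rnaseq_relabel"
  n_added <- 0L
  if (!is.null(new_dhs) && nrow(new_dhs) > 0) {
    keep <- best_overlap(bed_to_granges(new_dhs), rna) >= min_overlap
    add <- new_dhs[keep, , drop = FALSE]
    if (nrow(add)) {
      add$label <- "IR"
      add$source <- "rnaseq_new"
      common <- intersect(names(dataset), names(add))
      dataset <- rbind(dataset[common], add[common])
      n_added <- nrow(add)
    }
  }
  rownames(dataset) <- NULL
  list(dataset = dataset,
       summary = list(n_relabeled = sum(flip), n_added = n_added))
}

#' Reverse complement of a DNA string
#'
#' Alphabet `{A,C,G,T,N}`; `N` maps to `N`. An involution:
#' `revcomp(revcomp(s)) == s`.
#'
#' @param seq a DNA string.
#' @return the reverse complement string.
#' @export
revcomp <- function(seq) {
  check_dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Reverse-complement data augmentation
#'
#' Returns the original samples followed by one reverse-complemented copy of
#' each (ids suffixed `_rc`), label and metadata preserved; output order is
#' deterministic (original block, then complement block).
#'
#' @param samples manifest data.frame with columns `id` and `seq` (labels and
#'   any other columns carried through).
#' @return a data.frame of `2 * nrow(samples)` rows.
#' @export
augment_reverse_complement <- function(samples) {
  if (nrow(samples) == 0) return(samples)
  rc <- samples
  rc$id <- paste0(rc$id, "_rc")
  rc$seq <- vapply(samples$seq, revcomp, character(1), USE.NAMES = FALSE)
  out <- rbind(samples, rc)
  rownames(out) <- NULL
  out
}

#' Ungapped percent identity between two sequences
#'
#' The best ungapped alignment over all offsets of the shorter sequence within
#' the longer, on both strands; identity = matches / length of the shorter.
#'
#' @param a,b DNA strings.
#' @return identity in \[0, 1\].
#' @export
seq_identity <- function(a, b) {
  check_dna(a); check_dna(b)
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  ar <- charToRaw(a)
  la <- length(ar)
  best <- 0
  for (bs in c(b, revcomp(b))) {
    br <- charToRaw(bs)
    ns <- length(br)
    for (off in 0:(la - ns)) {
      best <- max(best, sum(ar[(off + 1L):(off + ns)] == br) / ns)
    }
  }
  best
}

#' Greedy redundancy clustering at an identity threshold
#'
#' Incremental greedy clustering in the spirit of CD-hit: sequences are
#' visited longest-first (ties broken lexicographically on the sequence); each
#' sequence joins the first existing cluster whose representative it matches
#' at `>= threshold` identity ([seq_identity], both strands), otherwise it
#' founds a new cluster. Fully deterministic.
#'
#' @param seqs character vector of sequences.
#' @param threshold identity threshold in (0, 1\]; default 0.80.
#' @return integer cluster assignment parallel to `seqs` (empty input gives an
#'   empty assignment); cluster ids are in founding order.
#' @export
reduce_redundancy <- function(seqs, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  n <- length(seqs)
  if (n == 0L) return(integer(0))
  ord <- order(-nchar(seqs), seqs)
  assign <- integer(n)
  reps <- integer(0)  # indices (into seqs) of cluster representatives
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(reps)) {
      if (seq_identity(seqs[reps[ci]], seqs[i]) >= threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, i)
      assign[i] <- length(reps)
    }
  }
  assign
}

#' Split-partition configuration
#'
#' @param fractions train/validation/test fractions; must sum to 1.
#' @param seed integer seed for the cluster-order shuffle.
#' @param redundancy_threshold identity threshold used for redundancy
#'   clustering (default 0.80).
#' @param min_rnaseq_overlap minimum overlap for the RNA-seq relabel rule, bp.
#' @return a `split_config` list.
#' @export
split_config <- function(fractions = c(train = 0.8, val = 0.1, test = 0.1),
                         seed = 1L, redundancy_threshold = 0.8,
                         min_rnaseq_overlap = 500L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1", call. = FALSE)
  stopifnot(redundancy_threshold > 0, redundancy_threshold <= 1)
  structure(list(fractions = fractions, seed = as.integer(seed),
                 redundancy_threshold = redundancy_threshold,
                 min_rnaseq_overlap = as.integer(min_rnaseq_overlap)),
            class = "split_config")
}

#' Cluster-aware train/validation/test split
#'
#' Whole clusters are assigned to a single partition, so no sequence at or
#' above the redundancy threshold to a test sequence ends up in train or
#' validation. Cluster order is shuffled with the config seed, then clusters
#' fill train up to its target fraction, then validation, with the remainder
#' going to test; partition sizes are therefore within one cluster's size of
#' the target fractions.
#'
#' @param n_samples number of samples (or a data.frame whose rows are samples).
#' @param clusters integer cluster assignment per sample (see
#'   [reduce_redundancy()]).
#' @param cfg a [split_config].
#' @return character vector (`"train"`/`"val"`/`"test"`) per sample.
#' @export
split_dataset <- function(n_samples, clusters, cfg = split_config()) {
  stopifnot(inherits(cfg, "split_config"))
  n <- if (is.data.frame(n_samples)) nrow(n_samples) else n_samples
  stopifnot(length(clusters) == n)
  ids <- unique(clusters)
  sizes <- table(factor(clusters, levels = ids))
  ord <- with_seed(derive_seed(cfg$seed, 53L), sample(seq_along(ids)))
  target_train <- cfg$fractions[1] * n
  target_trval <- (cfg$fractions[1] + cfg$fractions[2]) * n
  part <- character(length(ids))
  cum <- 0
  for (j in ord) {
    part[j] <- if (cum < target_train) "train"
               else if (cum < target_trval) "val"
               else "test"
    cum <- cum + sizes[[j]]
  }
  part[match(clusters, ids)]
}

#' One-hot encode a DNA sequence
#'
#' Rows in fixed order A, C, G, T; each unambiguous base gives a single 1 in
#' its column; `N` columns are all-zero (they contribute nothing to
#' convolution activations).
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @return a 4 x nchar(seq) binary matrix with rownames A,C,G,T.
#' @export
one_hot <- function(seq) {
  check_dna(seq)
  chars <- strsplit(seq, "")[[1]]
  m <- matrix(0, 4L, length(chars), dimnames = list(DNA_BASES, NULL))
  idx <- match(chars, DNA_BASES)  # N -> NA -> all-zero column
  keep <- !is.na(idx)
  m[cbind(idx[keep], which(keep))] <- 1
  m
}

#' One-hot encode a batch of equal-length sequences
#'
#' @param seqs character vector of equal-length DNA strings.
#' @return a 4 x L x n array.
#' @export
one_hot_batch <- function(seqs) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1L)
  x <- array(0, c(4L, L, length(seqs)))
  for (i in seq_along(seqs)) x[, , i] <- one_hot(seqs[[i]])
  x
}

#' Dataset bookkeeping arithmetic
#'
#' The accounting identity for the two-phase labeling: IR events found by
#' RNA-seq split into relabeled negatives (which conserve the total) and new
#' DHSs (which add to it); reverse-complement augmentation doubles every
#' count.
#'
#' @param annotation_ir,annotation_nonir event counts from the
#'   annotation-phase labeling.
#' @param rnaseq_new IR DHSs newly added from RNA-seq.
#' @param rnaseq_relabeled negatives flipped to IR by RNA-seq.
#' @return list with `ir_events_rnaseq` (new + relabeled), `total_ir`,
#'   `total_nonir`, `total_events`, `augmented_ir`, `augmented_nonir`, and
#'   `total_sequences`.
#' @export
dhs_summary <- function(annotation_ir, annotation_nonir,
                        rnaseq_new, rnaseq_relabeled) {
  annotation_ir <- as.integer(annotation_ir)
  annotation_nonir <- as.integer(annotation_nonir)
  rnaseq_new <- as.integer(rnaseq_new)
  rnaseq_relabeled <- as.integer(rnaseq_relabeled)
  total_ir <- annotation_ir + rnaseq_new + rnaseq_relabeled
  total_nonir <- annotation_nonir - rnaseq_relabeled
  list(
    ir_events_rnaseq = rnaseq_new + rnaseq_relabeled,
    total_ir = total_ir,
    total_nonir = total_nonir,
    total_events = total_ir + total_nonir,
    augmented_ir = 2L * total_ir,
    augmented_nonir = 2L * total_nonir,
    total_sequences = 2L * (total_ir + total_nonir)
  )
}

#' Fetch interval sequences from an in-memory genome
#'
#' @param genome named character vector of chromosome sequences.
#' @param gr intervals (`GRanges` or BED data.frame).
#' @return character vector of sequences.
#' @export
fetch_sequences <- function(genome, gr) {
  gr <- bed_to_granges(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  stopifnot(all(chrom %in% names(genome)))
  substring(genome[chrom], GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Build a labeled DHS manifest from a synthetic annotation
#'
#' Applies the annotation-phase overlap labeling (`min_overlap = 1`) to the
#' annotation's DHS intervals and attaches their sequences.
#'
#' @param ann a `synthetic_annotation` from [simulate_annotation()].
#' @param min_overlap labeling threshold in bp for the annotation phase.
#' @return manifest data.frame (id, chrom, start, end, strand, seq, label,
#'   source), BED coordinates.
#' @export
build_dhs_dataset <- function(ann, min_overlap = 1L) {
  stopifnot(inherits(ann, "synthetic_annotation"))
  dhs <- ann$dhs
  data.frame(
    id = dhs$name,
    chrom = as.character(GenomicRanges::seqnames(dhs)),
    start = GenomicRanges::start(dhs) - 1L,
    end = GenomicRanges::end(dhs),
    strand = as.character(GenomicRanges::strand(dhs)),
    seq = unname(fetch_sequences(ann$genome, dhs)),
    label = label_dhs(dhs, ann$retained_introns, min_overlap = min_overlap),
    source = "annotation",
    stringsAsFactors = FALSE
  )
}
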