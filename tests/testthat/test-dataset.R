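# Brute-force overlap of half-open intervals by counting shared positions.
bf_overlap <- function(a, b) length(intersect(seq(a[1], a[2] - 1), seq(b[1], b[2] - 1)))

test_that("label_dhs applies the half-open overlap rule", {
  dhs <- data.frame(chrom = "chr1", start = 1000, end = 1600)
  expect_identical(label_dhs(dhs, data.frame(chrom = "chr1", start = 900, end = 2000),
                             min_overlap = 500), "IR")
  # touching intervals share no position
  expect_identical(label_dhs(data.frame(chrom = "chr1", start = 0, end = 600),
                             data.frame(chrom = "chr1", start = 600, end = 1200),
                             min_overlap = 1), "nonIR")
})

test_that("labeling threshold is exact at the boundary (brute-force check)", {
  dhs <- c(0, 600)
  for (ri in list(c(101, 700), c(100, 700))) {
    ov <- bf_overlap(dhs, ri)
    got <- label_dhs(data.frame(chrom = "c", start = dhs[1], end = dhs[2]),
                     data.frame(chrom = "c", start = ri[1], end = ri[2]),
                     min_overlap = 500)
    expect_identical(got, if (ov >= 500) "IR" else "nonIR")
  }
  expect_error(bed_to_granges(data.frame(chrom = "c", start = 5, end = 5)),
               "malformed")
})

test_that("labeling is order-independent and idempotent", {
  set.seed(21)
  dhs <- data.frame(chrom = "c", start = seq(0, 1800, 200), end = seq(600, 2400, 200))
  ret <- data.frame(chrom = "c", start = c(100, 1500), end = c(800, 2100))
  l1 <- label_dhs(dhs, ret)
  l2 <- label_dhs(dhs, ret[2:1, ])
  expect_identical(l1, l2)
  expect_identical(label_dhs(dhs, ret), l1)
})

test_that("RNA-seq relabeling flips qualifying negatives and appends new DHSs", {
  manifest <- data.frame(
    id = c("d1", "d2"), chrom = "c", start = c(0, 5000), end = c(600, 5600),
    strand = "+", label = "nonIR", source = "annotation",
    stringsAsFactors = FALSE)
  rna <- data.frame(chrom = "c", start = 50, end = 900)  # 550 bp with d1
  out <- relabel_with_rnaseq(manifest, rna)
  expect_identical(out$summary$n_relabeled, 1L)
  expect_identical(out$dataset$label, c("IR", "nonIR"))
  expect_identical(out$dataset$source[1], "rnaseq_relabel")
  # empty RNA-seq set changes nothing
  out0 <- relabel_with_rnaseq(manifest, rna[0, ])
  expect_identical(out0$dataset$label, manifest$label)
  expect_identical(out0$summary, list(n_relabeled = 0L, n_added = 0L))
  # overlap of exactly 499 does not qualify
  rna499 <- data.frame(chrom = "c", start = 101, end = 900)
  expect_identical(relabel_with_rnaseq(manifest, rna499)$summary$n_relabeled, 0L)
  # new DHSs pass the same rule
  new <- data.frame(id = "n1", chrom = "c", start = 60, end = 660, strand = "+",
                    stringsAsFactors = FALSE)
  out2 <- relabel_with_rnaseq(manifest, rna, new_dhs = new)
  expect_identical(out2$summary$n_added, 1L)
  expect_identical(tail(out2$dataset$source, 1), "rnaseq_new")
  # duplicates between dataset and new_dhs are rejected
  dup <- data.frame(id = "n2", chrom = "c", start = 0, end = 600, strand = "+")
  expect_error(relabel_with_rnaseq(manifest, rna, new_dhs = dup), "duplicate")
})

test_that("relabeling never decreases the IR count", {
  set.seed(5)
  n <- 30
  manifest <- data.frame(
    id = paste0("d", 1:n), chrom = "c",
    start = seq(0, by = 1000, length.out = n),
    end = seq(600, by = 1000, length.out = n), strand = "+",
    label = sample(c("IR", "nonIR"), n, replace = TRUE), source = "annotation",
    stringsAsFactors = FALSE)
  rna <- data.frame(chrom = "c", start = sample(0:25000, 5), end = 0)
  rna$end <- rna$start + sample(500:2000, 5)
  out <- relabel_with_rnaseq(manifest, rna)
  expect_gte(sum(out$dataset$label == "IR"), sum(manifest$label == "IR"))
  expect_identical(sum(manifest$label == "IR" & out$dataset$label == "nonIR"), 0L)
})

test_that("revcomp is the base-complement involution", {
  expect_identical(revcomp("AACG"), "CGTT")
  expect_identical(revcomp("ACGT"), "ACGT")  # palindrome
  expect_identical(revcomp("ANNT"), "ANNT")
  set.seed(31)
  for (s in c(random_dna(5, 17), "NNN", "A")) {
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_error(revcomp("ACGU"), "alphabet|characters")
})

test_that("reverse-complement augmentation doubles every label count", {
  df <- data.frame(id = c("a", "b", "c"), seq = c("ACGT", "GGTA", "TTAA"),
                   label = c("IR", "nonIR", "IR"), stringsAsFactors = FALSE)
  out <- augment_reverse_complement(df)
  expect_identical(nrow(out), 6L)
  expect_identical(as.vector(table(out$label)), 2L * as.vector(table(df$label)))
  expect_identical(out$seq[1:3], df$seq)           # original block first
  expect_identical(out$seq[4], revcomp(df$seq[1])) # then complements in order
  expect_identical(nrow(augment_reverse_complement(df[0, ])), 0L)
})

test_that("dataset bookkeeping arithmetic is exact", {
  s <- dhs_summary(annotation_ir = 100, annotation_nonir = 400,
                   rnaseq_new = 30, rnaseq_relabeled = 5)
  expect_identical(s$total_ir, 135L)         # 100 + 30 + 5
  expect_identical(s$total_nonir, 395L)      # 400 - 5
  expect_identical(s$total_events, 530L)     # relabels conserve totals
  expect_identical(s$total_sequences, 1060L) # augmentation doubles
})

test_that("one_hot encodes A,C,G,T rows with all-zero N columns", {
  expect_identical(one_hot("A")[, 1], c(A = 1, C = 0, G = 0, T = 0))
  m <- one_hot("ACGN")
  expect_identical(unname(colSums(m)), c(1, 1, 1, 0))
  expect_identical(dim(one_hot(strrep("ACGT", 150))), c(4L, 600L))
  expect_error(one_hot("ACGX"), "characters")
})

test_that("one_hot of the reverse complement is the double flip", {
  set.seed(41)
  for (s in c(random_dna(4, 9), "ACGNNT")) {
    m <- one_hot(s)
    flipped <- m[4:1, ncol(m):1]
    dimnames(flipped) <- dimnames(m)
    expect_identical(one_hot(revcomp(s)), flipped)
  }
})
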