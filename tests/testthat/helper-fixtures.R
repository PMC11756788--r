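# Shared fixtures, built in code at test time.

# A near-deterministic PWM whose consensus is `consensus` (counts 97/1/1/1
# before the pseudocount), handy when a test needs a motif with a known
# best-scoring word.
consensus_pwm <- function(consensus, id = "TEST1", name = "TestTF") {
  bases <- strsplit(consensus, "")[[1]]
  counts <- matrix(1, 4, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[cbind(match(bases, rownames(counts)), seq_along(bases))] <- 97
  pwm(id, name, counts)
}

# Independent ungapped-identity oracle: plain character loops, no shared code
# with seq_identity().
oracle_identity <- function(a, b) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  if (nchar(a) < nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a)
  best <- 0
  for (bs in c(b, rc(b))) {
    ns <- nchar(bs)
    bv <- strsplit(bs, "")[[1]]
    av <- strsplit(a, "")[[1]]
    for (off in 0:(la - ns)) {
      m <- sum(av[(off + 1):(off + ns)] == bv) / ns
      if (m > best) best <- m
    }
  }
  best
}

# Random DNA of given length under the current RNG.
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# Tiny sequence model covering every layer type; deterministic per seed.
tiny_model <- function(seed = 4L, len = 12L) {
  with_seed(seed, nn_model(list(
    layer_conv1d(4, 3, 3), layer_batchnorm(3), layer_gelu(), layer_maxpool(2),
    layer_attention_pool(3), layer_dense(3, 2), layer_relu(),
    layer_dense(2, 1), layer_sigmoid()), c(4, len)))
}
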