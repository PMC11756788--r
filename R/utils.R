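#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Derive a child RNG seed from a master seed
#'
#' Each stochastic generator in the package draws from its own RNG stream,
#' seeded deterministically from the user-facing seed so that partial re-runs
#' of a pipeline reproduce the same draws. The derivation is a fixed
#' Lehmer-style hash kept within 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param stream small integer identifying the consumer stream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(stream) * 7919) %% 2147483629)
}

#' Run code under a local, seeded RNG without disturbing the caller's RNG
#'
#' @param seed integer seed for the local stream.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Check that a value is a single probability in [0, 1]
#' @noRd
check_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

#' Validate a DNA string over the {A,C,G,T,N} alphabet
#' @noRd
check_dna <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L) {
    stop("`seq` must be a single character string", call. = FALSE)
  }
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  invisible(seq)
}

#' Numerically stable logistic function
#' @param x numeric vector of logits.
#' @return probabilities in (0, 1).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))
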