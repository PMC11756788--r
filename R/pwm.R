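#' Position weight matrix with log-odds scoring
#'
#' Builds a PWM from a 4 x k count (or frequency) matrix, adding a pseudocount
#' per cell before normalisation, and precomputes the log-odds matrix against a
#' background base distribution together with the best achievable score
#' (`max_score`, the sum over columns of the per-column maximum log-odds).
#'
#' @param id motif identifier (e.g. a JASPAR accession).
#' @param name motif name (typically the transcription factor name).
#' @param counts numeric 4 x k matrix, rows in A,C,G,T order.
#' @param pseudocount value added to every cell before column normalisation.
#' @param background length-4 base probabilities (A,C,G,T); default uniform.
#' @return an object of class `pwm` with elements `id`, `name`, `probs`,
#'   `logodds`, `background`, `max_score` and `width`.
#' @export
pwm <- function(id, name, counts, pseudocount = 0.01, background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) stop("`counts` must have 4 rows (A,C,G,T)", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-8) {
    stop("`background` must be 4 probabilities summing to 1", call. = FALSE)
  }
  probs <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  rownames(probs) <- DNA_BASES
  logodds <- log(probs / background)
  structure(
    list(
      id = id, name = name, probs = probs, logodds = logodds,
      background = background, max_score = sum(apply(logodds, 2, max)),
      width = ncol(probs)
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s (%s), width %d, max log-odds %.3f>\n",
              x$id, x$name, x$width, x$max_score))
  invisible(x)
}

#' Read motifs from a JASPAR PFM flat file
#'
#' Parses the JASPAR text format: a `>ID NAME` header line followed by four
#' rows `A [ n n ... ]`, `C [...]`, `G [...]`, `T [...]`.
#'
#' @param path file path.
#' @inheritParams pwm
#' @return a named list of [pwm] objects, keyed by motif id.
#' @export
read_jaspar <- function(path, pseudocount = 0.01, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0L) stop("no JASPAR records found in ", path, call. = FALSE)
  out <- vector("list", length(headers))
  for (i in seq_along(headers)) {
    h <- strsplit(sub("^>\\s*", "", lines[headers[i]]), "\\s+")[[1]]
    id <- h[1]
    name <- if (length(h) > 1) paste(h[-1], collapse = " ") else h[1]
    rows <- lines[(headers[i] + 1):(headers[i] + 4)]
    counts <- t(vapply(rows, function(r) {
      nums <- regmatches(r, gregexpr("[0-9.]+", sub("^\\s*[ACGT]", "", r)))[[1]]
      as.numeric(nums)
    }, numeric(length(regmatches(rows[1],
      gregexpr("[0-9.]+", sub("^\\s*[ACGT]", "", rows[1])))[[1]]))))
    base_order <- sub("^\\s*([ACGT]).*", "\\1", rows)
    counts <- counts[match(DNA_BASES, base_order), , drop = FALSE]
    out[[i]] <- pwm(id, name, counts, pseudocount = pseudocount, background = background)
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  out
}

#' Write motifs to a JASPAR PFM flat file
#'
#' Probabilities are written scaled to counts out of 100 (JASPAR files carry
#' counts; the scale does not affect downstream scoring, which renormalises).
#'
#' @param pwms list of [pwm] objects.
#' @param path output file path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$name), con)
    cnt <- round(p$probs * 100, 2)
    for (b in seq_along(DNA_BASES)) {
      writeLines(sprintf("%s [ %s ]", DNA_BASES[b],
                         paste(format(cnt[b, ], trim = TRUE), collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Sample one motif instance from a PWM
#'
#' Draws each position independently from the PWM's column distribution.
#'
#' @param p a [pwm].
#' @return a character string of length `p$width`.
#' @export
sample_motif_instance <- function(p) {
  paste(vapply(seq_len(p$width), function(j) {
    sample(DNA_BASES, 1L, prob = p$probs[, j])
  }, character(1)), collapse = "")
}
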