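#' Interpretation configuration
#'
#' The selection and scanning thresholds for attribution-based motif
#' enrichment: sequences are kept when the model assigns their true class a
#' probability above `confidence_threshold`; positions are hot spots when
#' their attribution exceeds `hotspot_frac` of the per-sequence maximum; a
#' motif matches a hot spot when some covering window scores at least
#' `motif_score_frac` of the motif's best achievable log-odds.
#'
#' @param confidence_threshold probability threshold for confident sequences.
#' @param hotspot_frac fraction of the per-sequence maximum attribution.
#' @param motif_score_frac fraction of a motif's maximum log-odds score.
#' @param ig_steps Riemann steps for integrated gradients.
#' @param abs_attr use absolute attributions when extracting hot spots
#'   (default keeps signs, following the rule as written).
#' @return an `interpret_config` list.
#' @export
interpret_config <- function(confidence_threshold = 0.7, hotspot_frac = 0.7,
                             motif_score_frac = 0.8, ig_steps = 50L,
                             abs_attr = FALSE) {
  check_prob(confidence_threshold, "confidence_threshold")
  stopifnot(hotspot_frac > 0, hotspot_frac <= 1,
            motif_score_frac > 0, motif_score_frac <= 1, ig_steps >= 1)
  structure(list(confidence_threshold = confidence_threshold,
                 hotspot_frac = hotspot_frac,
                 motif_score_frac = motif_score_frac,
                 ig_steps = as.integer(ig_steps), abs_attr = abs_attr),
            class = "interpret_config")
}

#' Integrated gradients attribution for one sequence
#'
#' Right-Riemann approximation of the path integral of the model gradient
#' from a baseline to the input:
#' `IG_i = (x_i - b_i) * (1/m) * sum_{k=1..m} df/dx_i (b + (k/m)(x - b))`.
#' The default baseline is the all-zeros one-hot ("no sequence"). The
#' completeness axiom `sum(IG) = f(x) - f(baseline)` holds up to the
#' discretisation error of the Riemann sum, which shrinks as `steps` grows.
#'
#' @param model a differentiable scalar-output [nn_model()].
#' @param x one-hot input, `4 x N` matrix.
#' @param baseline baseline of the same shape (default zeros).
#' @param steps number of Riemann steps.
#' @return an `attribution_map`: list with `values` (`4 x N`), `model_prob`,
#'   `baseline_prob` and `completeness_gap`
#'   (`sum(values) - (f(x) - f(baseline))`).
#' @export
integrated_gradients <- function(model, x, baseline = NULL, steps = 50L) {
  stopifnot(steps >= 1)
  x <- as.matrix(x)
  if (is.null(baseline)) baseline <- x * 0
  baseline <- as.matrix(baseline)
  if (!identical(dim(x), dim(baseline))) {
    stop("`x` and `baseline` must have the same shape", call. = FALSE)
  }
  diffm <- x - baseline
  xb <- array(0, c(dim(x), steps))
  for (m in seq_len(steps)) xb[, , m] <- baseline + (m / steps) * diffm
  grads <- nn_input_gradient(model, xb)
  avg <- rowMeans(grads, dims = 2)
  values <- diffm * avg
  fx <- nn_predict(model, x)
  fb <- nn_predict(model, baseline)
  structure(list(values = values, model_prob = fx, baseline_prob = fb,
                 completeness_gap = sum(values) - (fx - fb)),
            class = "attribution_map")
}

#' Integrated gradients for a batch of sequences
#'
#' Same computation as [integrated_gradients()], evaluating the Riemann
#' interpolants of several sequences in one forward/backward pass per chunk.
#'
#' @param model scalar-output [nn_model()].
#' @param xs array `(4, N, n)` of one-hot sequences.
#' @param steps Riemann steps.
#' @param chunk sequences per pass (`chunk * steps` interpolants per batch).
#' @return array `(4, N, n)` of attributions.
#' @export
integrated_gradients_batch <- function(model, xs, steps = 50L, chunk = 4L) {
  d <- dim(xs)
  n <- d[3]
  out <- array(0, d)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    nb <- e - s + 1L
    big <- array(0, c(d[1], d[2], nb * steps))
    for (i in seq_len(nb)) {
      xi <- xs[, , s + i - 1L]
      for (m in seq_len(steps)) {
        big[, , (i - 1L) * steps + m] <- (m / steps) * xi  # zero baseline
      }
    }
    grads <- nn_input_gradient(model, big)
    for (i in seq_len(nb)) {
      g <- grads[, , ((i - 1L) * steps + 1L):(i * steps), drop = FALSE]
      out[, , s + i - 1L] <- xs[, , s + i - 1L] * rowMeans(g, dims = 2)
    }
  }
  out
}

#' Select confidently and correctly predicted samples
#'
#' A sample is kept when the model assigns its *true* class a probability
#' above the threshold: IR samples need `p > thr`, non-IR samples need
#' `1 - p > thr` (the rule applied symmetrically to both classes).
#'
#' @param probs predicted class-1 (IR) probabilities.
#' @param labels true labels (`"IR"`/`"nonIR"`, or 0/1).
#' @param threshold probability threshold.
#' @return logical keep vector; counts per class in attributes `n_ir_kept`
#'   and `n_nonir_kept`.
#' @export
select_confident <- function(probs, labels, threshold = 0.7) {
  stopifnot(length(probs) == length(labels))
  is_ir <- labels %in% c(1, "1", "IR", TRUE)
  keep <- ifelse(is_ir, probs > threshold, 1 - probs > threshold)
  structure(keep, n_ir_kept = sum(keep & is_ir),
            n_nonir_kept = sum(keep & !is_ir))
}

#' Extract attribution hot spots from one sequence
#'
#' The per-position scalar is the attribution at the observed base (the
#' nonzero one-hot channel; all-zero `N` columns contribute 0). Positions
#' whose scalar strictly exceeds `frac` times the per-sequence maximum of
#' these same scalars are hot spots. Signs are preserved by default, so a
#' sequence whose scalars are all non-positive yields no hot spots; set
#' `abs_attr` in the config for magnitude-based extraction. The output is
#' invariant to positive rescaling of the attribution map.
#'
#' @param values `4 x N` attribution matrix (an `attribution_map$values`).
#' @param onehot the matching `4 x N` one-hot input.
#' @param frac hot-spot fraction of the per-sequence maximum.
#' @param abs_attr take absolute attributions first.
#' @return data.frame with `position` (0-based) and `attribution`.
#' @export
extract_hot_spots <- function(values, onehot, frac = 0.7, abs_attr = FALSE) {
  stopifnot(frac > 0, frac <= 1, identical(dim(values), dim(onehot)))
  scalar <- colSums(values * onehot)
  if (abs_attr) scalar <- abs(scalar)
  if (!length(scalar) || all(onehot == 0)) {
    return(data.frame(position = integer(), attribution = numeric()))
  }
  mx <- max(scalar)
  keep <- which(scalar > frac * mx)
  data.frame(position = keep - 1L, attribution = scalar[keep])
}

#' Log-odds scan of a sequence with a PWM, both strands
#'
#' @param seq DNA string.
#' @param p a [pwm].
#' @return list `fwd`/`rev`: window scores for windows starting at 0-based
#'   positions `0..L-k`; `N` bases score 0 (background-neutral).
#' @keywords internal
#' @export
scan_sequence <- function(seq, p) {
  chars <- strsplit(seq, "")[[1]]
  idx <- match(chars, DNA_BASES)
  L <- length(chars)
  k <- p$width
  if (L < k) return(list(fwd = numeric(0), rev = numeric(0)))
  lo <- p$logodds
  lo_rc <- lo[4:1, k:1, drop = FALSE]  # reverse-strand scoring matrix
  nw <- L - k + 1L
  fwd <- numeric(nw)
  rev <- numeric(nw)
  for (j in seq_len(k)) {
    b <- idx[j:(j + nw - 1L)]
    vf <- lo[, j][b]
    vr <- lo_rc[, j][b]
    vf[is.na(vf)] <- 0
    vr[is.na(vr)] <- 0
    fwd <- fwd + vf
    rev <- rev + vr
  }
  list(fwd = fwd, rev = rev)
}

#' Does a motif match at a hot-spot position?
#'
#' Considers every window of the motif's width, on either strand, that covers
#' `center` and lies within the sequence; the hot spot matches if any such
#' window's log-odds score reaches `score_frac` of the motif's maximum score.
#'
#' @param seq DNA string.
#' @param center 0-based hot-spot position.
#' @param p a [pwm].
#' @param score_frac fraction of `p$max_score` required.
#' @return logical.
#' @export
scan_motif <- function(seq, center, p, score_frac = 0.8) {
  L <- nchar(seq)
  stopifnot(center >= 0, center < L)
  sc <- scan_sequence(seq, p)
  if (!length(sc$fwd)) return(FALSE)
  lo_start <- max(0L, center - p$width + 1L)
  hi_start <- min(center, L - p$width)
  if (lo_start > hi_start) return(FALSE)
  w <- (lo_start:hi_start) + 1L
  any(pmax(sc$fwd[w], sc$rev[w]) >= score_frac * p$max_score)
}

#' Hot-spot x motif match matrix
#'
#' Scans each sequence once per motif and then resolves every hot spot
#' against the windows covering it.
#'
#' @param hotspots data.frame with `seq_id` and `position` (0-based).
#' @param seqs named character vector of sequences.
#' @param pwms named list of [pwm] objects.
#' @param score_frac fraction of each motif's maximum score.
#' @return logical matrix, hot spots x motifs.
#' @export
motif_match_matrix <- function(hotspots, seqs, pwms, score_frac = 0.8) {
  m <- matrix(FALSE, nrow(hotspots), length(pwms),
              dimnames = list(NULL, names(pwms)))
  by_seq <- split(seq_len(nrow(hotspots)), hotspots$seq_id)
  for (sid in names(by_seq)) {
    s <- seqs[[sid]]
    L <- nchar(s)
    rows <- by_seq[[sid]]
    for (mi in seq_along(pwms)) {
      p <- pwms[[mi]]
      sc <- scan_sequence(s, p)
      if (!length(sc$fwd)) next
      hit <- pmax(sc$fwd, sc$rev) >= score_frac * p$max_score
      hitpos <- which(hit)  # 1-based window starts
      if (!length(hitpos)) next
      for (r in rows) {
        cen <- hotspots$position[r]
        lo <- max(0L, cen - p$width + 1L)
        hi <- min(cen, L - p$width)
        if (lo <= hi && any(hitpos >= lo + 1L & hitpos <= hi + 1L)) {
          m[r, mi] <- TRUE
        }
      }
    }
  }
  m
}

#' Motif enrichment in IR vs non-IR hot spots
#'
#' For each motif, `f_ir` is the fraction of IR-class hot spots the motif
#' matches and `f_nonir` the analogue for non-IR hot spots; the enrichment
#' score is their difference, in `[-1, 1]`. Records are ranked by score,
#' descending, ties broken by motif id.
#'
#' @param hotspots data.frame with `seq_id`, `position` (0-based) and
#'   `class` (`"IR"`/`"nonIR"`); both classes must contribute hot spots.
#' @param seqs named character vector of sequences.
#' @param pwms named list of [pwm] objects.
#' @param cfg an [interpret_config()].
#' @return data.frame (motif_id, name, f_ir, f_nonir, score, rank) with the
#'   hot-spot x motif match matrix in attribute `match_matrix` and the class
#'   indicator in attribute `is_ir`.
#' @export
enrichment_scores <- function(hotspots, seqs, pwms, cfg = interpret_config()) {
  is_ir <- hotspots$class %in% c("IR", 1, "1", TRUE)
  if (!any(is_ir) || all(is_ir)) {
    stop(sprintf("need hot spots in both classes (IR: %d, nonIR: %d)",
                 sum(is_ir), sum(!is_ir)), call. = FALSE)
  }
  mm <- motif_match_matrix(hotspots, seqs, pwms, cfg$motif_score_frac)
  f_ir <- colMeans(mm[is_ir, , drop = FALSE])
  f_nonir <- colMeans(mm[!is_ir, , drop = FALSE])
  out <- data.frame(
    motif_id = names(pwms),
    name = vapply(pwms, `[[`, character(1), "name"),
    f_ir = unname(f_ir), f_nonir = unname(f_nonir),
    score = unname(f_ir - f_nonir),
    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$motif_id), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "match_matrix") <- mm
  attr(out, "is_ir") <- is_ir
  out
}

#' Permutation null for enrichment scores
#'
#' Shuffles the hot-spot class labels and recomputes every motif's
#' enrichment score, giving a one-sided p-value
#' `(1 + #{perm >= observed}) / (n_perm + 1)` per motif. Permuted scores are
#' centered at zero under the null.
#'
#' @param match_matrix logical hot-spot x motif matrix
#'   (attribute of [enrichment_scores()] output).
#' @param is_ir logical class indicator per hot spot.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return data.frame (motif_id, observed, p_value) plus the permutation
#'   score matrix in attribute `perm_scores`.
#' @export
enrichment_permutation <- function(match_matrix, is_ir, n_perm = 1000L,
                                   seed = 1L) {
  obs <- colMeans(match_matrix[is_ir, , drop = FALSE]) -
    colMeans(match_matrix[!is_ir, , drop = FALSE])
  n <- length(is_ir)
  perm <- with_seed(derive_seed(seed, 97L), {
    vapply(seq_len(n_perm), function(i) {
      sh <- sample(is_ir)
      colMeans(match_matrix[sh, , drop = FALSE]) -
        colMeans(match_matrix[!sh, , drop = FALSE])
    }, numeric(ncol(match_matrix)))
  })
  perm <- matrix(perm, ncol(match_matrix), n_perm,
                 dimnames = list(colnames(match_matrix), NULL))
  p <- (1 + rowSums(perm >= obs)) / (n_perm + 1)
  out <- data.frame(motif_id = colnames(match_matrix), observed = unname(obs),
                    p_value = unname(p), stringsAsFactors = FALSE)
  attr(out, "perm_scores") <- perm
  out
}

#' Rank chromatin targets by logistic-regression weight
#'
#' Orders targets by signed weight (descending), carrying the per-target
#' protein and group. Because one protein can be assayed in several cell
#' types or conditions, it may occupy several ranks; protein-level reports
#' (e.g. the intersection of top-k and bottom-k proteins) are obtained with
#' [top_bottom_proteins()].
#'
#' @param model a fitted `lr_targets` (see [logistic_targets_model()]).
#' @param target_meta per-target metadata (`target`, `protein`, `group`);
#'   defaults to the metadata stored on the model.
#' @return data.frame (target, protein, group, weight, rank), sorted by
#'   weight descending; attribute `degenerate` flags an all-zero weight
#'   vector.
#' @export
rank_lr_targets <- function(model, target_meta = NULL) {
  stopifnot(inherits(model, "lr_targets"))
  meta <- target_meta %||% model$target_meta
  if (is.null(meta)) {
    meta <- data.frame(target = names(model$w), protein = names(model$w),
                       group = NA_character_, stringsAsFactors = FALSE)
  }
  if (nrow(meta) != length(model$w)) {
    stop("target metadata width does not match model weights", call. = FALSE)
  }
  out <- data.frame(target = meta$target, protein = meta$protein,
                    group = meta$group, weight = unname(model$w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$target), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  degenerate <- all(model$w == 0)
  if (degenerate) warning("all-zero weights: ranking is degenerate", call. = FALSE)
  attr(out, "degenerate") <- degenerate
  out
}

#' Proteins shared between the top-k and bottom-k of a target ranking
#'
#' @param ranking output of [rank_lr_targets()].
#' @param k list depth (e.g. 100).
#' @return character vector of proteins present in both lists.
#' @export
top_bottom_proteins <- function(ranking, k = 100L) {
  n <- nrow(ranking)
  k <- min(k, n)
  intersect(unique(ranking$protein[seq_len(k)]),
            unique(ranking$protein[seq(n - k + 1L, n)]))
}
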