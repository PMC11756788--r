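#' Training configuration
#'
#' Defaults mirror the protocol used for the sequence classifiers: a capped
#' number of epochs with validation-loss early stopping (100 epochs /
#' patience 10 for the CNNs; 1000 / 50 for the targets-based classifiers),
#' SGD with momentum 0.95 for fine-tuning or AdamW (with the optimiser's
#' conventional default weight decay, 0.01) elsewhere.
#'
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience, in epochs; must not exceed
#'   `max_epochs`.
#' @param optimizer `"adamw"` or `"sgd_momentum"`.
#' @param lr peak learning rate (the scheduler's `max_lr` when no explicit
#'   scheduler is given).
#' @param momentum SGD momentum.
#' @param weight_decay decoupled weight decay; `NULL` selects 0.01 for AdamW
#'   and 0 for SGD.
#' @param batch_size minibatch size.
#' @param imbalanced use the class-rebalancing sampler when drawing batches.
#' @param min_delta minimum decrease in validation loss that counts as an
#'   improvement.
#' @param seed integer seed fixing batch order and sampler draws.
#' @return a `train_config` list.
#' @export
train_config <- function(max_epochs = 100L, patience = 10L,
                         optimizer = c("adamw", "sgd_momentum"),
                         lr = 1e-3, momentum = 0.95, weight_decay = NULL,
                         batch_size = 64L, imbalanced = FALSE,
                         min_delta = 0, seed = 1L) {
  optimizer <- match.arg(optimizer)
  stopifnot(patience >= 1, patience <= max_epochs, batch_size >= 1)
  if (is.null(weight_decay)) {
    weight_decay <- if (optimizer == "adamw") 0.01 else 0
  }
  structure(list(max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), optimizer = optimizer,
                 lr = lr, momentum = momentum, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size), imbalanced = imbalanced,
                 min_delta = min_delta, seed = as.integer(seed)),
            class = "train_config")
}

#' Warmup + cosine learning-rate schedule configuration
#'
#' @param warmup_begin_lr learning rate at step 0.
#' @param max_lr peak rate reached after `warmup_steps`.
#' @param final_lr rate at `total_steps`.
#' @param warmup_steps length of the linear warmup, in optimiser steps.
#' @param total_steps total scheduled steps; must exceed `warmup_steps`.
#' @return a `scheduler_config` list.
#' @export
scheduler_config <- function(warmup_begin_lr, max_lr, final_lr,
                             warmup_steps, total_steps) {
  stopifnot(warmup_begin_lr <= max_lr, final_lr <= max_lr,
            warmup_steps < total_steps, warmup_steps >= 0)
  structure(list(warmup_begin_lr = warmup_begin_lr, max_lr = max_lr,
                 final_lr = final_lr, warmup_steps = as.integer(warmup_steps),
                 total_steps = as.integer(total_steps)),
            class = "scheduler_config")
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))`, with probabilities clipped to
#' `[eps, 1-eps]` for numerical stability.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y labels in \{0, 1\}.
#' @param eps clipping constant.
#' @return scalar loss.
#' @export
bce_loss <- function(p, y, eps = 1e-7) {
  if (length(p) != length(y)) stop("shape mismatch between `p` and `y`", call. = FALSE)
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Learning rate at a given optimiser step
#'
#' Linear interpolation from `warmup_begin_lr` to `max_lr` over
#' `[0, warmup_steps]`, then cosine decay
#' `final_lr + 0.5 (max_lr - final_lr) (1 + cos(pi t))` with
#' `t = (step - warmup_steps) / (total_steps - warmup_steps)`. Continuous at
#' the warmup boundary; monotone up then monotone down.
#'
#' @param step optimiser step in `[0, total_steps]` (vectorised).
#' @param cfg a [scheduler_config].
#' @return learning rate(s).
#' @export
lr_at <- function(step, cfg) {
  stopifnot(inherits(cfg, "scheduler_config"))
  if (any(step < 0) || any(step > cfg$total_steps)) {
    stop("step out of range [0, total_steps]", call. = FALSE)
  }
  ws <- cfg$warmup_steps
  warm <- if (ws > 0) {
    cfg$warmup_begin_lr + (cfg$max_lr - cfg$warmup_begin_lr) * step / ws
  } else {
    rep(cfg$max_lr, length(step))
  }
  t <- (step - ws) / (cfg$total_steps - ws)
  decay <- cfg$final_lr + 0.5 * (cfg$max_lr - cfg$final_lr) * (1 + cos(pi * t))
  ifelse(step <= ws, warm, decay)
}

#' Early-stopping decision from a validation-loss history
#'
#' Training stops once `patience` consecutive epochs have passed without a
#' strict improvement (decrease by more than `min_delta`) over the best
#' validation loss seen so far. Ties therefore do not reset the counter.
#'
#' @param val_losses numeric vector of per-epoch validation losses (possibly
#'   empty).
#' @param patience number of consecutive non-improving epochs tolerated.
#' @param min_delta minimum decrease that counts as improvement.
#' @return list with `stop` (logical) and `best_epoch` (1-based argmin; `NA`
#'   for an empty history).
#' @export
early_stopper <- function(val_losses, patience, min_delta = 0) {
  stopifnot(patience >= 1)
  n <- length(val_losses)
  if (n == 0L) return(list(stop = FALSE, best_epoch = NA_integer_))
  best <- Inf
  last_improve <- 0L
  for (i in seq_len(n)) {
    if (val_losses[i] < best - min_delta) {
      best <- val_losses[i]
      last_improve <- i
    }
  }
  list(stop = (n - last_improve) >= patience,
       best_epoch = which.min(val_losses))
}

#' Class-rebalancing index sampler
#'
#' Draws sample indices with replacement, with per-class probability inversely
#' proportional to class frequency, so each class contributes half of an
#' epoch's draws in expectation.
#'
#' @param labels 0/1 (or two-level) label vector.
#' @param n_draws number of indices to draw (default one epoch: one per
#'   sample).
#' @param seed integer seed.
#' @return integer vector of indices.
#' @export
imbalanced_sampler <- function(labels, n_draws = length(labels), seed = 1L) {
  tab <- table(labels)
  if (length(tab) < 2L) stop("imbalanced sampler needs both classes present", call. = FALSE)
  w <- 1 / (length(tab) * as.numeric(tab[as.character(labels)]))
  with_seed(derive_seed(seed, 71L), {
    sample.int(length(labels), n_draws, replace = TRUE, prob = w)
  })
}

# ---- optimisers ------------------------------------------------------------

opt_update <- function(layers, grads, lr, tcfg, t) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (!is.null(l$sub) && !is.null(g$sub)) {
      l$sub <- opt_update(l$sub, g$sub, lr, tcfg, t)
    }
    if (!is.null(l$params) && !is.null(g) && !isTRUE(l$frozen)) {
      if (is.null(l$opt)) l$opt <- list()
      for (pn in names(l$params)) {
        gr <- g[[pn]]
        if (is.null(gr)) next
        if (tcfg$optimizer == "adamw") {
          st <- l$opt[[pn]] %||% list(m = gr * 0, v = gr * 0)
          st$m <- 0.9 * st$m + 0.1 * gr
          st$v <- 0.999 * st$v + 0.001 * gr * gr
          mhat <- st$m / (1 - 0.9^t)
          vhat <- st$v / (1 - 0.999^t)
          l$params[[pn]] <- l$params[[pn]] -
            lr * (mhat / (sqrt(vhat) + 1e-8) + tcfg$weight_decay * l$params[[pn]])
          l$opt[[pn]] <- st
        } else {
          st <- l$opt[[pn]] %||% list(vel = gr * 0)
          st$vel <- tcfg$momentum * st$vel + gr
          l$params[[pn]] <- l$params[[pn]] - lr * st$vel -
            lr * tcfg$weight_decay * l$params[[pn]]
          l$opt[[pn]] <- st
        }
      }
    }
    layers[[i]] <- l
  }
  layers
}

#' Train a sigmoid-headed network
#'
#' Minibatch training with binary cross-entropy, the configured optimiser,
#' the warmup+cosine schedule (stepped per optimiser step), validation-loss
#' early stopping, and restoration of the best-epoch parameters at exit.
#'
#' @param model an [nn_model()] ending in a sigmoid unit.
#' @param train,val lists with elements `x` (array `(4, L, n)`) and `y`
#'   (0/1 labels).
#' @param tcfg a [train_config].
#' @param scfg a [scheduler_config]; if `NULL`, a default schedule is built
#'   with `max_lr = tcfg$lr`, warmup over the first 5% of steps,
#'   `warmup_begin_lr = max_lr / 10` and `final_lr = max_lr / 100`.
#' @return list with `model` (best-epoch weights) and `history` (data.frame
#'   epoch, train_loss, val_loss, lr, plus attributes `best_epoch` and
#'   `stopped_epoch`).
#' @export
fit <- function(model, train, val, tcfg = train_config(), scfg = NULL) {
  stopifnot(inherits(tcfg, "train_config"))
  vecmode <- identical(model$input_mode, "vec")
  n <- length(train$y)
  steps_per_epoch <- ceiling(n / tcfg$batch_size)
  if (is.null(scfg)) {
    total <- max(2L, steps_per_epoch * tcfg$max_epochs)
    scfg <- scheduler_config(tcfg$lr / 10, tcfg$lr, tcfg$lr / 100,
                             warmup_steps = max(1L, floor(0.05 * total)),
                             total_steps = total)
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), lr = numeric())
  best_model <- model
  best_epoch <- 0L
  step <- 0L
  for (epoch in seq_len(tcfg$max_epochs)) {
    idx <- if (tcfg$imbalanced) {
      imbalanced_sampler(train$y, n, seed = derive_seed(tcfg$seed, 100L + epoch))
    } else {
      with_seed(derive_seed(tcfg$seed, 100L + epoch), sample.int(n))
    }
    loss_sum <- 0
    epoch_lr <- NA_real_
    for (s in seq(1L, n, by = tcfg$batch_size)) {
      bi <- idx[s:min(s + tcfg$batch_size - 1L, n)]
      xb <- if (vecmode) train$x[, bi, drop = FALSE] else train$x[, , bi, drop = FALSE]
      yb <- train$y[bi]
      lr <- lr_at(min(step, scfg$total_steps), scfg)
      epoch_lr <- lr
      fwd <- nn_forward_pass(model, xb, train = TRUE)
      model <- fwd$model
      p <- drop(fwd$out)
      loss <- bce_loss(p, yb)
      if (!is.finite(loss)) {
        stop(sprintf("divergent loss (%s) at epoch %d; lower the learning rate",
                     format(loss), epoch), call. = FALSE)
      }
      loss_sum <- loss_sum + loss * length(bi)
      pc <- pmin(pmax(p, 1e-7), 1 - 1e-7)
      dp <- matrix((-yb / pc + (1 - yb) / (1 - pc)) / length(bi), 1L)
      bwd <- nn_backward_pass(model, fwd$caches, dp, need_input_grad = FALSE)
      model$layers <- opt_update(model$layers, bwd$grads, lr, tcfg, t = step + 1L)
      step <- step + 1L
    }
    val_loss <- bce_loss(nn_predict(model, val$x), val$y)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = loss_sum / n, val_loss = val_loss,
      lr = epoch_lr))
    if (val_loss < (if (best_epoch > 0) history$val_loss[best_epoch] else Inf)) {
      best_model <- model
      best_epoch <- epoch
    }
    es <- early_stopper(history$val_loss, tcfg$patience, tcfg$min_delta)
    if (es$stop) break
  }
  attr(history, "best_epoch") <- best_epoch
  attr(history, "stopped_epoch") <- nrow(history)
  list(model = best_model, history = history)
}

#' Train with seeded restarts
#'
#' From-scratch training of batch-normalised convolutional networks at a
#' high peak learning rate occasionally lands an initialisation in a dead
#' constant-output regime it cannot leave. This wrapper trains up to
#' `n_restarts` times, each attempt with its own derived initialisation and
#' batch-order seeds, keeps the attempt with the best validation loss, and
#' stops early once an attempt's validation loss clearly beats the trivial
#' constant predictor (`val_target`). Fully deterministic given `seed`.
#'
#' @param builder function(seed) returning a fresh [nn_model()].
#' @param train,val data lists as in [fit()].
#' @param tcfg_base a [train_config]; each attempt reuses it with a derived
#'   seed.
#' @param seed master seed.
#' @param n_restarts maximum number of attempts.
#' @param val_target validation loss below which the search stops.
#' @param warmup_frac fraction of total steps spent in linear warmup.
#' @return as [fit()], plus `attempts` (number of attempts run).
#' @export
fit_with_restarts <- function(builder, train, val, tcfg_base, seed = 1L,
                              n_restarts = 3L, val_target = 0.6,
                              warmup_frac = 0.15) {
  best <- NULL
  attempts <- 0L
  for (a in seq_len(n_restarts)) {
    attempts <- a
    tca <- tcfg_base
    tca$seed <- derive_seed(seed, 700L + 2L * a)
    steps <- ceiling(length(train$y) / tca$batch_size) * tca$max_epochs
    scfg <- scheduler_config(tca$lr / 10, tca$lr, tca$lr / 100,
                             warmup_steps = max(1L, floor(warmup_frac * steps)),
                             total_steps = steps)
    cand <- fit(builder(derive_seed(seed, 800L + 2L * a)), train, val, tca, scfg)
    if (is.null(best) ||
        min(cand$history$val_loss) < min(best$history$val_loss)) {
      best <- cand
    }
    if (min(best$history$val_loss) < val_target) break
  }
  best$attempts <- attempts
  best
}
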