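#' Basset-style convolutional classifier
#'
#' Three convolution / batch-norm / ReLU / max-pool blocks followed by three
#' fully connected layers ending in one sigmoid unit; the classic
#' peak-classification CNN architecture for open-chromatin sequences.
#'
#' @param input_len input sequence length in bp (default 600, the DHS unit).
#' @param conv_channels,kernels,pools per-block channel counts, kernel widths
#'   and pool widths (length 3 each); the input length must be divisible by
#'   the pool widths in sequence.
#' @param dense_units hidden sizes of the first two dense layers.
#' @param seed integer seed for weight initialisation.
#' @return an [nn_model()]; its parameter count is in `$meta$n_params`.
#' @export
basset_like <- function(input_len = 600L, conv_channels = c(32L, 32L, 48L),
                        kernels = c(12L, 8L, 8L), pools = c(3L, 5L, 5L),
                        dense_units = c(64L, 32L), seed = 1L) {
  stopifnot(length(conv_channels) == 3, length(kernels) == 3, length(pools) == 3)
  with_seed(derive_seed(seed, 81L), {
    layers <- list()
    in_ch <- 4L
    len <- input_len
    for (i in 1:3) {
      layers <- c(layers, list(
        layer_conv1d(in_ch, conv_channels[i], kernels[i]),
        layer_batchnorm(conv_channels[i]),
        layer_relu(),
        layer_maxpool(pools[i])))
      in_ch <- conv_channels[i]
      if (len %% pools[i] != 0) {
        stop("input length incompatible with pooling factors", call. = FALSE)
      }
      len <- len %/% pools[i]
    }
    layers <- c(layers, list(
      layer_flatten(),
      layer_dense(in_ch * len, dense_units[1]), layer_relu(),
      layer_dense(dense_units[1], dense_units[2]), layer_relu(),
      layer_dense(dense_units[2], 1L),
      layer_sigmoid()))
    nn_model(layers, c(4L, input_len))
  })
}

#' Basenji-style convolutional classifier
#'
#' One linear (un-activated) convolutional stem, six conv blocks pairing a
#' linear convolution + batch norm with a GELU non-linearity (the first
#' `n_pooled` blocks also max-pool), three dilated convolutional blocks with
#' residual skip connections and dilation doubling per block, then the same
#' fine-tuning block used on pre-trained backbones: convolution, attention
#' pooling, a dense layer and the sigmoid output.
#'
#' @param input_len input sequence length (must be divisible by
#'   `3 * 2^n_pooled`).
#' @param stem_channels,block_channels channel widths.
#' @param n_pooled how many of the six conv blocks downsample by 2.
#' @param head fine-tuning head configuration, a [finetune_head_config()].
#' @param seed integer seed.
#' @return an [nn_model()].
#' @export
basenji_like <- function(input_len = 600L, stem_channels = 24L,
                         block_channels = 32L, n_pooled = 3L,
                         head = finetune_head_config(conv_channels = 48L,
                                                     dense_units = 32L),
                         seed = 1L) {
  with_seed(derive_seed(seed, 83L), {
    layers <- list(
      layer_conv1d(4L, stem_channels, 12L),       # linear stem
      layer_batchnorm(stem_channels),
      layer_maxpool(3L))
    len <- input_len
    if (len %% 3L != 0) stop("input length incompatible with pooling factors", call. = FALSE)
    len <- len %/% 3L
    in_ch <- stem_channels
    for (i in 1:6) {
      layers <- c(layers, list(
        layer_conv1d(in_ch, block_channels, 5L),  # linear conv
        layer_batchnorm(block_channels),
        layer_gelu()))                            # non-linear path
      in_ch <- block_channels
      if (i <= n_pooled) {
        if (len %% 2L != 0) {
          stop("input length incompatible with pooling factors", call. = FALSE)
        }
        layers <- c(layers, list(layer_maxpool(2L)))
        len <- len %/% 2L
      }
    }
    for (i in 1:3) {
      layers <- c(layers, list(layer_residual(list(
        layer_gelu(),
        layer_conv1d(in_ch, in_ch, 3L, dilation = 2L^i),
        layer_batchnorm(in_ch)))))
    }
    layers <- c(layers, finetune_block_layers(in_ch, head))
    nn_model(layers, c(4L, input_len))
  })
}

#' Fine-tuning head configuration
#'
#' The architecture appended to a pre-trained backbone for binary
#' classification: one convolutional layer, attention (or mean) pooling over
#' positions, one dense layer, and a sigmoid output unit.
#'
#' @param conv_channels channels of the added convolution.
#' @param kernel its kernel width.
#' @param dense_units hidden size of the dense layer.
#' @param pooling `"attention"` or `"mean"`.
#' @return a `finetune_head_config` list.
#' @export
finetune_head_config <- function(conv_channels = 128L, kernel = 8L,
                                 dense_units = 64L,
                                 pooling = c("attention", "mean")) {
  structure(list(conv_channels = as.integer(conv_channels),
                 kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units),
                 pooling = match.arg(pooling)),
            class = "finetune_head_config")
}

finetune_block_layers <- function(in_ch, cfg) {
  stopifnot(inherits(cfg, "finetune_head_config"))
  pool_layer <- if (cfg$pooling == "attention") {
    layer_attention_pool(cfg$conv_channels)
  } else {
    layer_mean_pool()
  }
  list(
    layer_conv1d(in_ch, cfg$conv_channels, cfg$kernel),
    layer_gelu(),
    pool_layer,
    layer_dense(cfg$conv_channels, cfg$dense_units),
    layer_relu(),
    layer_dense(cfg$dense_units, 1L),
    layer_sigmoid())
}

#' Validate the backbone contract
#'
#' A backbone is an [nn_model()] that maps a one-hot batch to a feature map
#' `(channels x reduced length)`, is deterministic in eval mode and
#' differentiable end-to-end, and exposes its downsampling factor and
#' receptive field in `$meta`.
#'
#' @param backbone candidate model.
#' @return invisibly `TRUE`; errors describe the violated requirement.
#' @export
check_backbone <- function(backbone) {
  if (!inherits(backbone, "nn_model")) stop("backbone must be an nn_model", call. = FALSE)
  if (!identical(backbone$output_mode, "seq")) {
    stop("backbone output rank mismatch: expected a (channels x length) feature map",
         call. = FALSE)
  }
  if (is.null(backbone$meta$downsample) || is.null(backbone$meta$receptive_field)) {
    stop("backbone must expose downsample / receptive_field metadata", call. = FALSE)
  }
  invisible(TRUE)
}

#' Miniature convolutional backbone
#'
#' A small two-block conv/batch-norm/ReLU/max-pool embedder standing behind
#' the backbone contract; adapter slots for large pre-trained chromatin
#' backbones take the same form.
#'
#' @param input_len input length in bp.
#' @param channels,kernels,pools per-block settings (length 2 each).
#' @param seed integer seed.
#' @return an [nn_model()] with feature-map output.
#' @export
mini_backbone <- function(input_len = 600L, channels = c(16L, 24L),
                          kernels = c(8L, 6L), pools = c(4L, 5L), seed = 1L) {
  with_seed(derive_seed(seed, 85L), {
    layers <- list()
    in_ch <- 4L
    for (i in 1:2) {
      layers <- c(layers, list(
        layer_conv1d(in_ch, channels[i], kernels[i]),
        layer_batchnorm(channels[i]),
        layer_relu(),
        layer_maxpool(pools[i])))
      in_ch <- channels[i]
    }
    nn_model(layers, c(4L, input_len))
  })
}

#' Attach a classification head to a pre-trained backbone
#'
#' Two modes are supported. `"block"` appends the fine-tuning block
#' (convolution, attention pooling, dense layer, sigmoid). `"replace"`
#' emulates swapping a pre-trained model's classification layer for a binary
#' one: the feature map is flattened straight into a single sigmoid unit.
#' With `frozen = TRUE` the backbone layers are excluded from optimisation
#' (and their normalisation statistics held fixed), so backbone parameters
#' are bit-identical before and after training.
#'
#' @param backbone an [nn_model()] satisfying [check_backbone()].
#' @param cfg a [finetune_head_config()] (ignored in `"replace"` mode).
#' @param mode `"block"` or `"replace"`.
#' @param frozen freeze the backbone.
#' @param seed integer seed for head initialisation.
#' @return an [nn_model()] ending in a sigmoid unit; the number of backbone
#'   layers is recorded in `$meta$n_backbone_layers`.
#' @export
finetune_head <- function(backbone, cfg = finetune_head_config(),
                          mode = c("block", "replace"), frozen = FALSE,
                          seed = 1L) {
  check_backbone(backbone)
  mode <- match.arg(mode)
  in_ch <- backbone$output_shape[1]
  out_len <- backbone$output_shape[2]
  head <- with_seed(derive_seed(seed, 87L), {
    if (mode == "block") {
      finetune_block_layers(in_ch, cfg)
    } else {
      list(layer_flatten(), layer_dense(in_ch * out_len, 1L), layer_sigmoid())
    }
  })
  model <- nn_model(c(backbone$layers, head), backbone$input_shape)
  if (frozen) model <- nn_freeze(model, seq_along(backbone$layers))
  model$meta$n_backbone_layers <- length(backbone$layers)
  model
}

#' Logistic regression on chromatin targets
#'
#' A single dense layer with sigmoid output trained through the package's
#' training protocol: binary cross-entropy, AdamW with weak decoupled L2
#' (stabilising the weights that downstream ranking interprets), the
#' class-rebalancing sampler, and validation-loss early stopping.
#'
#' @param X samples x targets matrix (values in \[0, 1\]); no missing values.
#' @param labels 0/1 labels (both classes required).
#' @param target_meta optional per-target metadata (data.frame with columns
#'   `target`, `protein`, `group`) carried on the fitted object for ranking.
#' @param l2 L2 regularisation strength.
#' @param tcfg a [train_config]; the default mirrors the targets-classifier
#'   protocol (up to 1000 epochs, patience 50, imbalanced sampler).
#' @param val_frac fraction held out internally for early stopping.
#' @param seed integer seed.
#' @return an object of class `lr_targets` with elements `w` (named weight
#'   vector), `b`, `history`, `target_meta`.
#' @export
logistic_targets_model <- function(X, labels, target_meta = NULL, l2 = 1e-4,
                                   tcfg = NULL, val_frac = 0.15, seed = 1L) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in targets matrix", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("constant label vector", call. = FALSE)
  stopifnot(nrow(X) == length(labels))
  if (is.null(tcfg)) {
    tcfg <- train_config(max_epochs = 1000L, patience = 50L,
                         optimizer = "adamw", lr = 0.05, weight_decay = l2,
                         batch_size = 128L, imbalanced = TRUE, seed = seed)
  } else {
    tcfg$weight_decay <- l2
  }
  p <- ncol(X)
  model <- with_seed(derive_seed(seed, 91L), {
    nn_model(list(layer_dense(p, 1L), layer_sigmoid()), p)
  })
  n <- nrow(X)
  vi <- with_seed(derive_seed(seed, 93L),
                  sample.int(n, max(2L, round(val_frac * n))))
  # guard: both classes in both folds, else fall back to a stratified pick
  if (length(unique(labels[vi])) < 2L || length(unique(labels[-vi])) < 2L) {
    pos <- which(labels == max(labels)); neg <- which(labels == min(labels))
    vi <- c(pos[1], neg[1])
  }
  xt <- t(X)
  res <- fit(model,
             train = list(x = xt[, -vi, drop = FALSE], y = labels[-vi]),
             val = list(x = xt[, vi, drop = FALSE], y = labels[vi]),
             tcfg = tcfg)
  w <- drop(res$model$layers[[1]]$params$W)
  names(w) <- colnames(X)
  structure(list(w = w, b = res$model$layers[[1]]$params$b,
                 history = res$history, target_meta = target_meta,
                 model = res$model),
            class = "lr_targets")
}

#' @export
predict.lr_targets <- function(object, newdata, ...) {
  sigmoid(drop(as.matrix(newdata) %*% object$w) + object$b)
}

#' @export
print.lr_targets <- function(x, ...) {
  cat(sprintf("<lr_targets: %d targets, %d training epochs>\n",
              length(x$w), nrow(x$history)))
  invisible(x)
}

#' Subset a targets matrix by chromatin group
#'
#' @param X samples x targets matrix with column names.
#' @param target_meta data.frame with columns `target` and
#'   `group` (values in TF / HM / ACC), one row per column of `X`.
#' @param group `"ALL"` (identity), `"TF"`, `"HM"` or `"ACC"`.
#' @return list with the column-subset `targets` matrix and matching
#'   `target_meta`; column order is preserved.
#' @export
subset_targets <- function(X, target_meta, group = c("ALL", "TF", "HM", "ACC")) {
  group <- match.arg(group)
  stopifnot(ncol(X) == nrow(target_meta))
  bad <- setdiff(unique(target_meta$group), c("TF", "HM", "ACC"))
  if (length(bad)) stop("unknown target group(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (group == "ALL") {
    return(list(targets = X, target_meta = target_meta))
  }
  keep <- target_meta$group == group
  list(targets = X[, keep, drop = FALSE],
       target_meta = target_meta[keep, , drop = FALSE])
}

#' Gradient-boosted decision-tree configuration
#'
#' Defaults follow the printed settings of the boosted-trees targets
#' classifier: 1000 trees, unlimited depth with 50 leaves grown leaf-wise,
#' per-iteration bagging, unbalanced mode on.
#'
#' @param n_estimators number of trees.
#' @param max_depth maximum depth (-1 = unlimited).
#' @param num_leaves maximum leaves per tree.
#' @param bagging_freq bagging frequency (1 = every iteration).
#' @param unbalanced_mode reweight classes by inverse prevalence.
#' @param learning_rate shrinkage.
#' @param seed integer seed.
#' @return a `gbdt_config` list.
#' @export
gbdt_config <- function(n_estimators = 1000L, max_depth = -1L, num_leaves = 50L,
                        bagging_freq = 1L, unbalanced_mode = TRUE,
                        learning_rate = 0.1, seed = 1L) {
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 num_leaves = as.integer(num_leaves),
                 bagging_freq = as.integer(bagging_freq),
                 unbalanced_mode = unbalanced_mode,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "gbdt_config")
}

#' Gradient-boosted trees on chromatin targets
#'
#' Leaf-wise boosted decision trees (xgboost, `grow_policy = "lossguide"`)
#' at the configured settings, with `scale_pos_weight` implementing the
#' unbalanced mode. Per-feature gain importances are exposed for ranking.
#'
#' @inheritParams logistic_targets_model
#' @param cfg a [gbdt_config].
#' @return object of class `gbdt_targets` with `booster`, `importance`
#'   (named per-feature gain vector, zeros for unused features) and
#'   `target_meta`.
#' @export
gbdt_targets_model <- function(X, labels, target_meta = NULL,
                               cfg = gbdt_config()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("missing values in targets matrix", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("constant label vector", call. = FALSE)
  spw <- if (cfg$unbalanced_mode) sum(labels == 0) / sum(labels == 1) else 1
  params <- list(
    objective = "binary:logistic",
    tree_method = "hist",
    grow_policy = "lossguide",
    max_leaves = cfg$num_leaves,
    max_depth = if (cfg$max_depth < 0) 0L else cfg$max_depth,
    eta = cfg$learning_rate,
    scale_pos_weight = spw,
    nthread = 1L,
    seed = cfg$seed)
  dtrain <- xgboost::xgb.DMatrix(X, label = labels)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = cfg$n_estimators, verbose = 0)
  imp <- rep(0, ncol(X))
  names(imp) <- colnames(X)
  tab <- xgboost::xgb.importance(model = booster)
  if (!is.null(tab) && nrow(tab)) imp[tab$Feature] <- tab$Gain
  structure(list(booster = booster, importance = imp, cfg = cfg,
                 target_meta = target_meta),
            class = "gbdt_targets")
}

#' @export
predict.gbdt_targets <- function(object, newdata, ...) {
  stats::predict(object$booster, xgboost::xgb.DMatrix(as.matrix(newdata)))
}
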