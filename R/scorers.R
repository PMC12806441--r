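#' Scorer architecture configuration
#'
#' Two families are supported, mirroring the two branches of the model
#' architecture: a recurrent family (per-sequence LSTM encoders over embedded
#' residue indices, final hidden states concatenated into a fully connected
#' head ending in a single sigmoid unit) and a convolutional family
#' (per-sequence 1-D convolutions over one-hot matrices with ReLU and global
#' max pooling per filter size, concatenated into the same head).
#'
#' @param family `"recurrent"` or `"convolutional"`.
#' @param embed_dim Embedding width (recurrent family).
#' @param hidden_dim LSTM hidden width per encoder (recurrent family).
#' @param conv_filter_sizes Window lengths of the convolution filters
#'   (convolutional family).
#' @param conv_channels Channels per filter size (convolutional family).
#' @param head_layers Widths of the fully connected head layers.
#' @param dropout Dropout fraction in `[0, 1)`, applied to the concatenated
#'   feature vector feeding the head during training.
#' @return A `scorer_config`.
#' @export
scorer_config <- function(family = c("recurrent", "convolutional"),
                          embed_dim = 10L, hidden_dim = 64L,
                          conv_filter_sizes = c(2L, 3L, 4L), conv_channels = 32L,
                          head_layers = c(64L, 16L), dropout = 0.1) {
  family <- match.arg(family)
  embed_dim <- as.integer(embed_dim); hidden_dim <- as.integer(hidden_dim)
  conv_filter_sizes <- as.integer(conv_filter_sizes)
  conv_channels <- as.integer(conv_channels)
  head_layers <- as.integer(head_layers)
  if (family == "convolutional") {
    if (!length(conv_filter_sizes) || any(conv_filter_sizes < 1L))
      stop("conv_filter_sizes must be positive window lengths", call. = FALSE)
    if (conv_channels < 1L) stop("conv_channels must be positive", call. = FALSE)
  } else {
    if (embed_dim < 1L || hidden_dim < 1L)
      stop("embed_dim and hidden_dim must be positive", call. = FALSE)
  }
  if (!length(head_layers) || any(head_layers < 1L))
    stop("head_layers must be positive widths", call. = FALSE)
  if (!is.numeric(dropout) || dropout < 0 || dropout >= 1)
    stop("dropout must lie in [0, 1)", call. = FALSE)
  structure(list(family = family, embed_dim = embed_dim, hidden_dim = hidden_dim,
                 conv_filter_sizes = conv_filter_sizes, conv_channels = conv_channels,
                 head_layers = head_layers, dropout = dropout),
            class = "scorer_config")
}

#' Training configuration
#'
#' @param epochs Maximum epochs (>= 1).
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Adam step size.
#' @param seed Integer seed controlling initialization order, shuffling and
#'   dropout; fixed seed implies bit-reproducible training.
#' @param early_stop_patience Epochs without validation ROC-AUC improvement
#'   before stopping (best-epoch parameters are restored).
#' @param loss Only `"binary-cross-entropy"` is supported.
#' @return A `training_config`.
#' @export
training_config <- function(epochs = 100L, batch_size = 64L, learning_rate = 1e-3,
                            seed = 1L, early_stop_patience = 10L,
                            loss = "binary-cross-entropy") {
  epochs <- as.integer(epochs); batch_size <- as.integer(batch_size)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  loss <- match.arg(loss, "binary-cross-entropy")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 early_stop_patience = as.integer(early_stop_patience), loss = loss),
            class = "training_config")
}

cfg_for_cpp <- function(config) {
  list(family = config$family, embed_dim = config$embed_dim,
       hidden_dim = config$hidden_dim, conv_filter_sizes = config$conv_filter_sizes,
       conv_channels = config$conv_channels, head_layers = config$head_layers)
}

scorer_layout <- function(config) nn_param_layout(cfg_for_cpp(config))

feature_dim <- function(config) {
  if (config$family == "convolutional")
    2L * length(config$conv_filter_sizes) * config$conv_channels
  else 2L * config$hidden_dim
}

# draw parameters for the rows of `layout` in order, consuming the current RNG
# stream; uniform(-1/sqrt(fan_in), +) weights, zero biases, +1 LSTM forget bias
draw_params <- function(layout, config) {
  out <- numeric(sum(layout$length))
  for (i in seq_len(nrow(layout))) {
    name <- layout$name[i]; n <- layout$length[i]
    off <- layout$offset[i]
    if (grepl("_b_|^head_b|^lstm_b_|^conv_b_", name) || grepl("^head_bout$", name)) {
      vals <- numeric(n)
      if (grepl("^lstm_b_", name)) {
        H <- config$hidden_dim
        vals[(H + 1):(2 * H)] <- 1 # forget-gate bias
      }
    } else {
      s <- 1 / sqrt(layout$d1[i])
      vals <- stats::runif(n, -s, s)
    }
    out[off:(off + n - 1)] <- vals
  }
  out
}

#' Build a scorer (untrained)
#'
#' Initializes the parameter vector deterministically from `seed`: identical
#' `(config, seed)` yields bitwise-identical parameters. Untrained scorers
#' already produce valid probabilities (sigmoid output) but refuse to predict
#' unless `allow_untrained = TRUE` is passed to [predict.tcr_scorer()].
#'
#' @param config A [scorer_config].
#' @param scheme An [encoding_scheme].
#' @param seed Integer initialization seed.
#' @return A `tcr_scorer`.
#' @export
build_scorer <- function(config, scheme = encoding_scheme(), seed = 1L) {
  stopifnot(inherits(config, "scorer_config"), inherits(scheme, "encoding_scheme"))
  layout <- scorer_layout(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  params <- draw_params(layout, config)
  structure(list(config = config, scheme = scheme, params = params,
                 layout = layout, trained = FALSE, seed = as.integer(seed),
                 frozen = character(0), history = NULL,
                 provenance = "built", format_version = "tcrbind-ckpt-1"),
            class = "tcr_scorer")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.tcr_scorer <- function(x, ...) {
  cat(sprintf("<tcr_scorer> %s family, %d parameters, %s (provenance: %s)\n",
              x$config$family, length(x$params),
              if (x$trained) "trained" else "untrained", x$provenance))
  if (!is.null(x$history))
    cat(sprintf("  best validation ROC-AUC %.4f at epoch %d of %d run\n",
                max(x$history$val_auc), which.max(x$history$val_auc),
                nrow(x$history)))
  invisible(x)
}

# indices of parameters belonging to the given layer groups
group_indices <- function(layout, groups) {
  rows <- which(layout$group %in% groups)
  unlist(lapply(rows, function(i) layout$offset[i]:(layout$offset[i] + layout$length[i] - 1)))
}

check_two_classes <- function(dataset, what) {
  if (is.null(dataset$label) || any(is.na(dataset$label)))
    stop(what, " must be fully labeled", call. = FALSE)
  if (length(unique(dataset$label)) < 2)
    stop(what, " contains a single class; both binders and non-binders are required",
         call. = FALSE)
}

#' Train a scorer
#'
#' Minimizes binary cross-entropy by mini-batch Adam, with early stopping on
#' validation ROC-AUC (best-epoch parameters restored). Fully reproducible
#' from `tconf$seed`. Layers listed in the scorer's `frozen` field (set by
#' [transfer_parameters()]) are left bitwise unchanged.
#'
#' @param scorer A `tcr_scorer` from [build_scorer()] or
#'   [transfer_parameters()].
#' @param train_set,valid_set Labeled `binding_dataset`s containing both
#'   classes.
#' @param tconf A [training_config].
#' @param verbose Print per-epoch progress.
#' @return The trained `tcr_scorer`, with a `history` data frame of per-epoch
#'   train/validation loss and validation ROC-AUC.
#' @export
train_scorer <- function(scorer, train_set, valid_set, tconf = training_config(),
                         verbose = FALSE) {
  stopifnot(inherits(scorer, "tcr_scorer"), inherits(tconf, "training_config"))
  check_two_classes(train_set, "training set")
  if (nrow(valid_set) == 0) stop("validation set is empty", call. = FALSE)
  if (is.null(valid_set$label) || any(is.na(valid_set$label)) ||
      length(unique(valid_set$label)) < 2)
    stop("validation set must be labeled with both classes (early stopping uses ROC-AUC)",
         call. = FALSE)

  cfg <- cfg_for_cpp(scorer$config)
  enc_tr <- encode_dataset(train_set, scorer$scheme)
  enc_va <- encode_dataset(valid_set, scorer$scheme)
  y <- as.numeric(train_set$label)
  n <- length(y)
  Fdim <- feature_dim(scorer$config)
  p_drop <- scorer$config$dropout
  frozen_idx <- if (length(scorer$frozen)) group_indices(scorer$layout, scorer$frozen) else integer(0)

  params <- scorer$params
  m <- numeric(length(params)); v <- numeric(length(params)); tstep <- 0
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; lr <- tconf$learning_rate

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(tconf$seed)

  best_auc <- -Inf; best_params <- params; best_epoch <- 0L; wait <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), val_auc = numeric(0))

  for (epoch in seq_len(tconf$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = tconf$batch_size)
    tl <- 0
    for (s in starts) {
      idx <- perm[s:min(s + tconf$batch_size - 1, n)]
      B <- length(idx)
      mask <- if (p_drop > 0)
        matrix((stats::runif(B * Fdim) >= p_drop) / (1 - p_drop), B, Fdim)
      else NULL
      # pads are inert under masking, so batches can be trimmed to the longest
      # true length without changing any result
      wc <- seq_len(max(enc_tr$lc[idx])); wp <- seq_len(max(enc_tr$lp[idx]))
      r <- nn_eval(cfg, params, enc_tr$Xc[idx, wc, drop = FALSE], enc_tr$lc[idx],
                   enc_tr$Xp[idx, wp, drop = FALSE], enc_tr$lp[idx],
                   y[idx], mask, TRUE)
      g <- r$grad
      if (length(frozen_idx)) g[frozen_idx] <- 0
      tstep <- tstep + 1
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      params <- params - lr * (m / (1 - b1^tstep)) / (sqrt(v / (1 - b2^tstep)) + eps)
      tl <- tl + r$loss * B
    }
    va <- predict_encoded(cfg, params, enc_va)
    vy <- as.numeric(valid_set$label)
    pc <- pmin(pmax(va, 1e-12), 1 - 1e-12)
    vloss <- mean(-(vy * log(pc) + (1 - vy) * log(1 - pc)))
    vauc <- roc_auc(vy, va)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tl / n,
                                   val_loss = vloss, val_auc = vauc))
    if (verbose)
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val AUC %.4f",
                      epoch, tl / n, vloss, vauc))
    if (vauc > best_auc) {
      best_auc <- vauc; best_params <- params; best_epoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tconf$early_stop_patience) break
    }
  }

  scorer$params <- best_params
  scorer$trained <- TRUE
  scorer$history <- hist
  scorer$best_epoch <- best_epoch
  scorer$train_seed <- tconf$seed
  scorer$provenance <- paste0(scorer$provenance, "+trained")
  scorer
}

predict_encoded <- function(cfg, params, enc, batch_size = 512L) {
  n <- length(enc$lc)
  if (!n) return(numeric(0))
  out <- numeric(n)
  for (s in seq(1, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1, n)
    wc <- seq_len(max(enc$lc[idx])); wp <- seq_len(max(enc$lp[idx]))
    out[idx] <- nn_eval(cfg, params, enc$Xc[idx, wc, drop = FALSE], enc$lc[idx],
                        enc$Xp[idx, wp, drop = FALSE], enc$lp[idx])$scores
  }
  out
}

#' Predict binding probabilities
#'
#' Deterministic, batch-size independent scores in `[0, 1]`, in input order.
#'
#' @param object A trained `tcr_scorer`.
#' @param newdata A `binding_dataset` (labels, if any, are ignored).
#' @param batch_size Evaluation batch size (does not affect results).
#' @param allow_untrained Permit scoring with an untrained scorer.
#' @param ... Unused.
#' @return Numeric vector of probabilities.
#' @export
predict.tcr_scorer <- function(object, newdata, batch_size = 512L,
                               allow_untrained = FALSE, ...) {
  if (!object$trained && !allow_untrained)
    stop("scorer is untrained; pass allow_untrained = TRUE to score anyway",
         call. = FALSE)
  enc <- encode_dataset(newdata, object$scheme)
  predict_encoded(cfg_for_cpp(object$config), object$params, enc,
                  batch_size = as.integer(batch_size))
}

#' Save / load a scorer checkpoint
#'
#' A checkpoint is a single-file archive holding the parameter vector, the
#' architecture config, the encoding scheme, training seed, provenance and a
#' format-version string, so a model is loadable for prediction without the
#' original configuration.
#'
#' @param object A `tcr_scorer` or `tcr_ensemble`.
#' @param path Checkpoint file path.
#' @return `path` (save) or the restored object (load).
#' @export
save_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "tcr_scorer") || inherits(object, "tcr_ensemble"))
  saveRDS(object, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "tcr_scorer") && !inherits(obj, "tcr_ensemble"))
    stop("not a tcrbind checkpoint: ", path, call. = FALSE)
  if (inherits(obj, "tcr_scorer") && !identical(obj$format_version, "tcrbind-ckpt-1"))
    stop("unsupported checkpoint format: ", obj$format_version, call. = FALSE)
  obj
}

#' Stratified 10-fold cross-validation with best-fold selection
#'
#' Partitions the dataset into 10 stratified validation folds (class ratio
#' preserved within one sample), trains one model per fold on the remaining
#' nine, and returns all fold metrics plus the model from the fold with the
#' highest validation ROC-AUC (ties broken toward the lower fold index). The
#' partition is reproducible from `tconf$seed`.
#'
#' @param dataset Labeled `binding_dataset` with at least 10 samples per class.
#' @param config A [scorer_config].
#' @param tconf A [training_config].
#' @param scheme An [encoding_scheme].
#' @param n_folds Number of folds (default 10).
#' @param verbose Print per-fold progress.
#' @return A `cv_result`: `fold_metrics` (list of [metrics_report]s),
#'   `fold_assignment` (validation fold per sample), `best_fold_index`
#'   (1-based), `best_model`.
#' @export
crossvalidate_10fold <- function(dataset, config, tconf = training_config(),
                                 scheme = encoding_scheme(), n_folds = 10L,
                                 verbose = FALSE) {
  check_two_classes(dataset, "cross-validation dataset")
  n_folds <- as.integer(n_folds)
  y <- dataset$label
  if (min(table(y)) < n_folds)
    stop(sprintf("stratified %d-fold needs at least %d samples of each class (have %d)",
                 n_folds, n_folds, min(table(y))), call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(tconf$seed)
  fold <- integer(nrow(dataset))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(n_folds), length(idx))
  }
  .Random.seed_restore(old)

  fold_metrics <- vector("list", n_folds)
  fold_models <- vector("list", n_folds)
  aucs <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    tr <- subset_bd(dataset, which(fold != k))
    va <- subset_bd(dataset, which(fold == k))
    model <- build_scorer(config, scheme, seed = tconf$seed + k)
    model <- train_scorer(model, tr, va, tconf)
    sc <- predict(model, va)
    fold_metrics[[k]] <- compute_metrics(va$label, sc)
    fold_models[[k]] <- model
    aucs[k] <- fold_metrics[[k]]$roc_auc
    if (verbose) message(sprintf("fold %d/%d: validation ROC-AUC %.4f", k, n_folds, aucs[k]))
  }
  best <- which.max(aucs) # which.max returns the first maximum: lower-index tie rule
  structure(list(fold_metrics = fold_metrics, fold_assignment = fold,
                 fold_aucs = aucs, best_fold_index = best,
                 best_model = fold_models[[best]]),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds; validation ROC-AUCs: %s; best fold %d\n",
              length(x$fold_metrics),
              paste(sprintf("%.3f", x$fold_aucs), collapse = " "),
              x$best_fold_index))
  invisible(x)
}
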