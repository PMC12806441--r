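#' Transfer parameters from a source-task scorer
#'
#' Initializes a target-task scorer of identical architecture from a trained
#' source scorer: all parameters are copied bitwise; the fully connected head
#' is reinitialized from `seed` when `reinit_head = TRUE`; layer groups named
#' in `frozen_layers` (`"enc_cdr3"`, `"enc_pep"`, `"head"`) are marked
#' non-trainable for subsequent fine-tuning. By default the whole parameter
#' set, head included, is transferred and nothing is frozen. Provenance is
#' recorded in the returned scorer.
#'
#' @param source A trained `tcr_scorer`.
#' @param reinit_head Reinitialize the head instead of copying it.
#' @param frozen_layers Character vector of layer-group names to freeze.
#' @param seed Seed for head reinitialization.
#' @param target_config Optional [scorer_config] for the target; must be
#'   identical to the source architecture (checked dimension by dimension).
#' @return An initialized, untrained `tcr_scorer` ready for [fine_tune()].
#' @export
transfer_parameters <- function(source, reinit_head = FALSE,
                                frozen_layers = character(0), seed = 1L,
                                target_config = NULL) {
  stopifnot(inherits(source, "tcr_scorer"))
  if (!source$trained) stop("source scorer must be trained before transfer", call. = FALSE)
  if (!is.null(target_config)) {
    a <- cfg_for_cpp(source$config); b <- cfg_for_cpp(target_config)
    used <- if (a$family == "convolutional")
      c("family", "conv_filter_sizes", "conv_channels", "head_layers")
    else c("family", "embed_dim", "hidden_dim", "head_layers")
    for (f in used)
      if (!identical(a[[f]], b[[f]]))
        stop(sprintf("architecture mismatch on '%s': source %s vs target %s", f,
                     paste(a[[f]], collapse = ","), paste(b[[f]], collapse = ",")),
             call. = FALSE)
  }
  known <- unique(source$layout$group)
  bad <- setdiff(frozen_layers, known)
  if (length(bad))
    stop("unknown frozen-layer name(s): ", paste(bad, collapse = ", "),
         "; available: ", paste(known, collapse = ", "), call. = FALSE)

  target <- source
  target$trained <- FALSE
  target$history <- NULL
  target$frozen <- frozen_layers
  target$provenance <- paste0("transfer(", source$provenance,
                              if (reinit_head) ", reinit_head" else "",
                              if (length(frozen_layers))
                                paste0(", frozen=", paste(frozen_layers, collapse = "+"))
                              else "", ")")
  if (reinit_head) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    fresh <- draw_params(target$layout, target$config)
    idx <- group_indices(target$layout, "head")
    target$params[idx] <- fresh[idx]
  }
  target
}

#' Fine-tune a transferred (or scratch) scorer on the target task
#'
#' Identical training contract to [train_scorer()]; frozen layer groups stay
#' bitwise unchanged. Provided as the named fine-tuning step of the transfer
#' workflow; scratch-initialized scorers are accepted for controls.
#'
#' @param initialized A `tcr_scorer` from [transfer_parameters()] or
#'   [build_scorer()].
#' @param target_train,target_valid Labeled target-task `binding_dataset`s.
#' @param tconf A [training_config].
#' @param verbose Print per-epoch progress.
#' @return The fine-tuned `tcr_scorer`.
#' @export
fine_tune <- function(initialized, target_train, target_valid,
                      tconf = training_config(), verbose = FALSE) {
  if (nrow(target_train) == 0) stop("target training set is empty", call. = FALSE)
  train_scorer(initialized, target_train, target_valid, tconf, verbose = verbose)
}

#' Combine scorers into an ensemble
#'
#' Two combiners are provided. `"avg"` is the unweighted arithmetic mean of
#' member probabilities (the published final combiner). `"sub"` is a weighted
#' mean with nonnegative per-member weights summing to one, typically fitted
#' on a calibration set with [fit_sub_ensemble_weights()]; its construction is
#' this package's own determinate stand-in, not a published definition.
#'
#' @param members List of >= 2 trained `tcr_scorer`s sharing one encoding
#'   scheme.
#' @param mode `"avg"` or `"sub"`.
#' @param sub_weights Per-member weights (sub mode only): nonnegative, summing
#'   to 1.
#' @return A `tcr_ensemble`.
#' @export
ensemble_scorer <- function(members, mode = c("avg", "sub"), sub_weights = NULL) {
  mode <- match.arg(mode)
  if (length(members) < 2) stop("an ensemble needs at least 2 members", call. = FALSE)
  for (m in members) {
    stopifnot(inherits(m, "tcr_scorer"))
    if (!identical(unclass(m$scheme), unclass(members[[1]]$scheme)))
      stop("ensemble members must share one encoding scheme", call. = FALSE)
  }
  if (mode == "sub") {
    if (is.null(sub_weights)) stop("sub mode requires sub_weights", call. = FALSE)
    if (length(sub_weights) != length(members) || any(sub_weights < 0) ||
        abs(sum(sub_weights) - 1) > 1e-8)
      stop("sub_weights must be nonnegative, one per member, summing to 1", call. = FALSE)
  } else sub_weights <- NULL
  structure(list(members = members, mode = mode, sub_weights = sub_weights),
            class = "tcr_ensemble")
}

#' @export
print.tcr_ensemble <- function(x, ...) {
  cat(sprintf("<tcr_ensemble> %s mode, %d members (%s)%s\n", x$mode, length(x$members),
              paste(vapply(x$members, function(m) m$config$family, ""), collapse = " + "),
              if (!is.null(x$sub_weights))
                paste0(", weights ", paste(sprintf("%.2f", x$sub_weights), collapse = "/"))
              else ""))
  invisible(x)
}

#' Predict with an ensemble
#'
#' Avg mode returns the unweighted arithmetic mean of member probabilities;
#' sub mode the weighted mean. Output always lies between the elementwise
#' minimum and maximum of the member scores.
#'
#' @param object A `tcr_ensemble` with trained members.
#' @param newdata A `binding_dataset`.
#' @param ... Passed to the member [predict.tcr_scorer()] calls.
#' @return Numeric vector of probabilities.
#' @export
predict.tcr_ensemble <- function(object, newdata, ...) {
  for (m in object$members)
    if (!m$trained) stop("all ensemble members must be trained", call. = FALSE)
  sc <- vapply(object$members, function(m) predict(m, newdata, ...),
               numeric(nrow(newdata)))
  sc <- matrix(sc, nrow = nrow(newdata))
  if (object$mode == "avg") rowMeans(sc)
  else as.numeric(sc %*% object$sub_weights)
}

#' @rdname predict.tcr_ensemble
#' @param ens A `tcr_ensemble`.
#' @param pairs A `binding_dataset`.
#' @export
ensemble_predict <- function(ens, pairs, ...) predict(ens, pairs, ...)

#' Fit sub-ensemble weights on a calibration set
#'
#' Exhaustive search over the weight simplex at the given grid step,
#' maximizing calibration ROC-AUC; ties are broken toward the weights closest
#' to uniform (then toward the first grid point in enumeration order), so the
#' result is deterministic. Identical members therefore receive uniform
#' weights.
#'
#' @param members List of >= 2 trained `tcr_scorer`s.
#' @param calib Labeled `binding_dataset` with both classes present.
#' @param step Grid step on the simplex (default 0.01 for 2 members; coarser
#'   steps are advisable for > 3 members).
#' @return Numeric weight vector summing to 1.
#' @export
fit_sub_ensemble_weights <- function(members, calib, step = 0.01) {
  if (length(members) < 2) stop("need at least 2 members", call. = FALSE)
  if (nrow(calib) == 0) stop("calibration set is empty", call. = FALSE)
  check_two_classes(calib, "calibration set")
  sc <- vapply(members, function(m) predict(m, calib), numeric(nrow(calib)))
  sc <- matrix(sc, nrow = nrow(calib))
  k <- length(members)
  grid <- simplex_grid(k, step)
  y <- calib$label
  best_auc <- -Inf; best_dist <- Inf; best_w <- rep(1 / k, k)
  unif <- rep(1 / k, k)
  for (i in seq_len(nrow(grid))) {
    w <- grid[i, ]
    auc <- roc_auc(y, as.numeric(sc %*% w))
    d <- sum((w - unif)^2)
    if (auc > best_auc + 1e-12 || (abs(auc - best_auc) <= 1e-12 && d < best_dist - 1e-12)) {
      best_auc <- auc; best_dist <- d; best_w <- w
    }
  }
  best_w
}

# all nonnegative k-vectors on the unit simplex with coordinates multiple of step
simplex_grid <- function(k, step) {
  m <- round(1 / step)
  if (k == 2) {
    w1 <- (0:m) / m
    return(cbind(w1, 1 - w1, deparse.level = 0))
  }
  rec <- function(k, total) {
    if (k == 1) return(matrix(total, ncol = 1))
    out <- list()
    for (i in 0:total)
      out[[i + 1]] <- cbind(i, rec(k - 1, total - i), deparse.level = 0)
    do.call(rbind, out)
  }
  rec(k, m) / m
}
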