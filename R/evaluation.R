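#' ROC-AUC via the rank-sum identity
#'
#' Equals the Mann-Whitney probability that a random positive outscores a
#' random negative, with 0.5 credit for ties.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric vector of the same length.
#' @return ROC-AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("ROC-AUC undefined: labels contain a single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' PR-AUC by the average-precision convention
#'
#' Sum over descending distinct score thresholds of
#' (recall gain) x (precision at the threshold). Tied scores enter as one
#' block, making the value deterministic under ties.
#'
#' @inheritParams roc_auc
#' @return Average precision in `(0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch", call. = FALSE)
  n1 <- sum(labels == 1)
  if (n1 == 0 || sum(labels == 0) == 0)
    stop("PR-AUC undefined: labels contain a single class", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  grp_end <- which(diff(s) != 0)
  grp_end <- c(grp_end, length(s))
  tp <- cumsum(y)[grp_end]
  np <- grp_end
  prec <- tp / np
  dtp <- diff(c(0, tp))
  sum(dtp / n1 * prec)
}

#' Classification metrics report
#'
#' Threshold-free ranking metrics (ROC-AUC with 0.5 tie credit, PR-AUC by
#' average precision) plus hard-call metrics at the given probability
#' threshold (predicted positive iff score >= threshold).
#'
#' @param labels Binary 0/1 vector; both classes must be present.
#' @param scores Probabilities in `[0, 1]`.
#' @param threshold Hard-call threshold (default 0.5).
#' @return A `metrics_report`: `roc_auc`, `pr_auc`, `precision`, `recall`,
#'   `f1`, `accuracy`, `confusion` (TP/FP/TN/FN), `threshold`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) stop("length mismatch", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  rauc <- roc_auc(labels, scores)
  pauc <- pr_auc(labels, scores)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  structure(list(roc_auc = rauc, pr_auc = pauc, precision = precision,
                 recall = recall, f1 = f1,
                 accuracy = (tp + tn) / length(labels),
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 threshold = threshold),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> ROC-AUC %.4f  PR-AUC %.4f  acc %.4f  P %.3f  R %.3f  F1 %.3f (thr %.2f)\n",
              x$roc_auc, x$pr_auc, x$accuracy, x$precision, x$recall, x$f1, x$threshold))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n",
              x$confusion["TP"], x$confusion["FP"], x$confusion["TN"], x$confusion["FN"]))
  invisible(x)
}

#' Negative sampling by shuffling TCRs against peptides
#'
#' For each peptide with `p` positive pairs, draws `round(ratio * p)` TCRs
#' uniformly without replacement from the pool, excluding every TCR positively
#' paired with that peptide anywhere in `positives`, and labels the new pairs
#' 0. The combined dataset is shuffled deterministically by `seed`. Generated
#' negatives can never collide with a positive pair.
#'
#' @param positives `binding_dataset` of positive (label 1) pairs.
#' @param tcr_pool Character vector of candidate CDR3beta sequences.
#' @param ratio Negatives per positive (default 1.0, i.e. class balance).
#' @param seed Integer seed.
#' @return A shuffled labeled `binding_dataset` of positives plus generated
#'   negatives.
#' @export
negative_sample <- function(positives, tcr_pool, ratio = 1.0, seed = 1L) {
  stopifnot(inherits(positives, "binding_dataset"))
  if (!is.null(positives$label) && any(positives$label != 1))
    stop("`positives` must contain only label-1 pairs", call. = FALSE)
  if (ratio <= 0) stop("ratio must be positive", call. = FALSE)
  pool <- unique(tcr_pool)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  neg_c <- character(0); neg_p <- character(0)
  for (pep in unique(positives$peptide)) {
    p <- sum(positives$peptide == pep)
    need <- round(ratio * p)
    excl <- unique(positives$cdr3b[positives$peptide == pep])
    avail <- setdiff(pool, excl)
    if (length(avail) < need)
      stop(sprintf("TCR pool exhausted for peptide %s: need %d negatives, only %d eligible TCRs",
                   pep, need, length(avail)), call. = FALSE)
    draw <- avail[sample.int(length(avail), need)]
    neg_c <- c(neg_c, draw); neg_p <- c(neg_p, rep(pep, need))
  }
  all_c <- c(positives$cdr3b, neg_c)
  all_p <- c(positives$peptide, neg_p)
  all_y <- c(rep(1, nrow(positives)), rep(0, length(neg_c)))
  ord <- sample.int(length(all_y))
  binding_dataset(all_c[ord], all_p[ord], all_y[ord],
                  provenance = paste0(attr(positives, "provenance"), "+shuffled-negatives"),
                  validate = FALSE)
}

#' Partition validation pairs by peptide seen/unseen status
#'
#' A validation pair goes to the shared-peptide set iff its peptide occurs in
#' any training pair; otherwise to the unique-peptide set. The two outputs
#' partition the validation set. Generalization to unique (unseen) peptides is
#' the hard open problem in TCR specificity prediction.
#'
#' @param validation,training Labeled `binding_dataset`s.
#' @return List with `shared` and `unique` datasets; peptide counts per side
#'   are attached as attributes `n_peptides_shared` / `n_peptides_unique`.
#' @export
split_seen_unseen <- function(validation, training) {
  stopifnot(inherits(validation, "binding_dataset"), inherits(training, "binding_dataset"))
  seen <- validation$peptide %in% unique(training$peptide)
  shared <- subset_bd(validation, which(seen))
  uniq <- subset_bd(validation, which(!seen))
  attr(shared, "provenance") <- "shared-peptide"
  attr(uniq, "provenance") <- "unique-peptide"
  out <- list(shared = shared, unique = uniq)
  attr(out, "n_peptides_shared") <- length(unique(shared$peptide))
  attr(out, "n_peptides_unique") <- length(unique(uniq$peptide))
  out
}

#' Filter validation pairs by sequence similarity to training data
#'
#' Removes validation pairs whose CDR3beta (default; `side = "peptide"`
#' filters on the peptide instead) reaches normalized similarity
#' `max_similarity` or higher to any training sequence of the same side, where
#' `similarity(a, b) = 1 - edit_distance(a, b) / max(nchar(a), nchar(b))`.
#' Retained pairs thus sit strictly below the threshold; at
#' `max_similarity = 1` exactly the duplicated sequences are removed. Lowering
#' the threshold never retains a pair removed at a higher one.
#'
#' @param validation,training `binding_dataset`s.
#' @param max_similarity Threshold in `(0, 1]`.
#' @param side `"cdr3b"` or `"peptide"`.
#' @return The retained validation subset; removed/retained counts are
#'   reported via `message()`.
#' @export
similarity_filter <- function(validation, training, max_similarity,
                              side = c("cdr3b", "peptide")) {
  side <- match.arg(side)
  if (!is.numeric(max_similarity) || max_similarity <= 0 || max_similarity > 1)
    stop("max_similarity must lie in (0, 1]", call. = FALSE)
  vs <- validation[[side]]
  ts <- unique(training[[side]])
  if (!length(ts) || !nrow(validation)) {
    message("similarity_filter: retained ", nrow(validation), ", removed 0")
    return(validation)
  }
  uv <- unique(vs)
  d <- utils::adist(uv, ts)
  denom <- outer(nchar(uv), nchar(ts), pmax)
  sim <- 1 - d / denom
  maxsim <- apply(sim, 1, max)
  keep_seq <- uv[maxsim < max_similarity]
  keep <- vs %in% keep_seq
  message(sprintf("similarity_filter (%s, threshold %.2f): retained %d, removed %d",
                  side, max_similarity, sum(keep), sum(!keep)))
  subset_bd(validation, which(keep))
}

#' Linear k-mer co-occurrence baseline
#'
#' A deliberately simple reference classifier: every (CDR3beta k-mer, peptide
#' k-mer) combination observed in a labeled pair is tallied per class, scored
#' by its smoothed log positive/negative odds, and a test pair is scored by
#' the maximum weight over its own combinations (0 for unseen combinations).
#' On noiseless motif tasks this baseline is near-perfect, certifying that the
#' task is learnable; trained-scorer failures then indicate implementation
#' bugs rather than impossible tasks. Scores are real-valued (for ranking
#' metrics), not probabilities.
#'
#' @param train Labeled `binding_dataset`.
#' @param test `binding_dataset` to score.
#' @param k k-mer length (default 3).
#' @param alpha Additive smoothing (default 1).
#' @return Numeric score per test pair.
#' @export
kmer_baseline <- function(train, test, k = 3L, alpha = 1) {
  check_two_classes(train, "baseline training set")
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1), k:n))
  }
  combos_of <- function(cdr3, pep) {
    kc <- kmers(cdr3); kp <- kmers(pep)
    if (!length(kc) || !length(kp)) return(character(0))
    as.vector(outer(kc, kp, paste, sep = "|"))
  }
  per_row <- lapply(seq_len(nrow(train)),
                    function(i) combos_of(train$cdr3b[i], train$peptide[i]))
  all_combos <- unlist(per_row, use.names = FALSE)
  all_labels <- rep(train$label, lengths(per_row))
  counts <- rowsum(cbind(pos = all_labels, neg = 1 - all_labels), group = all_combos)
  w <- log((counts[, "pos"] + alpha) / (counts[, "neg"] + alpha))
  vapply(seq_len(nrow(test)), function(i) {
    cb <- combos_of(test$cdr3b[i], test$peptide[i])
    ww <- w[match(cb, rownames(counts))]
    ww[is.na(ww)] <- 0
    max(c(0, ww))
  }, numeric(1))
}
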