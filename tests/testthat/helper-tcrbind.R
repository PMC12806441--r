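# shared fixtures: small architectures and tasks that train in seconds

small_conv <- function() scorer_config("convolutional", conv_filter_sizes = c(2L, 3L),
                                       conv_channels = 8L, head_layers = c(16L, 8L),
                                       dropout = 0.1)

small_lstm <- function() scorer_config("recurrent", embed_dim = 6L, hidden_dim = 12L,
                                       head_layers = c(16L, 8L), dropout = 0.1)

quick_tconf <- function(epochs = 3L, seed = 1L)
  training_config(epochs = epochs, batch_size = 32L, seed = seed,
                  early_stop_patience = 5L)

single_motif_task <- function(seed = 11L)
  make_task(synthetic_task_spec(n_motif_pairs = 1L, seed = seed))

# a random valid sequence for tests
rand_aa <- function(len) paste(sample(tcrbind::AA_ALPHABET, len, replace = TRUE),
                               collapse = "")

# independent Wagner-Fischer dynamic-programming oracle for Levenshtein distance
dp_edit_distance <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0L, n + 1, m + 1)
  D[, 1] <- 0:n; D[1, ] <- 0:m
  for (i in seq_len(n))
    for (j in seq_len(m))
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + (x[i] != y[j]))
  D[n + 1, m + 1]
}

# brute-force Mann-Whitney ROC-AUC with 0.5 tie credit
bf_roc_auc <- function(labels, scores) {
  ps <- scores[labels == 1]; ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(ps) * length(ns))
}

# scorer stand-in with an injectable scoring function, for rank/scan tests
mock_scorer <- function(fn) structure(list(fn = fn, trained = TRUE),
                                      class = "mock_scorer")
predict.mock_scorer <- function(object, newdata, ...) object$fn(newdata)
registerS3method("predict", "mock_scorer", predict.mock_scorer,
                 envir = asNamespace("stats"))

# force a built scorer to be usable for prediction (random but deterministic)
as_trained <- function(scorer) { scorer$trained <- TRUE; scorer }
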