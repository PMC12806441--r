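#' Specification of a synthetic motif-governed binding task
#'
#' A synthetic task emulates the structure of collected TCR-peptide binding
#' data with an auditable ground truth: a set of (TCR motif, peptide motif)
#' pairs defines the binding rule — a pair binds iff, for some motif pair, the
#' TCR motif occurs as a substring of the CDR3beta AND the peptide motif
#' occurs as a substring of the peptide. The source regime mimics MHC class I
#' epitopes (~9-mer peptides, abundant data); the target regime mimics MHC
#' class II (~15-mer peptides, scarce data); a shared fraction of motif pairs
#' gives the two tasks partially shared binding determinants so transfer can
#' carry signal.
#'
#' @param n_motif_pairs Number of motif pairs defining the rule.
#' @param motif_len_tcr,motif_len_pep Motif lengths in residues (defaults 3).
#' @param peptide_len Length-2 integer range for sampled peptide lengths
#'   (source default `c(8, 10)`; use `c(13, 17)` for the target regime).
#' @param cdr3_len Length-2 integer range for sampled CDR3beta lengths
#'   (default `c(12, 18)`).
#' @param shared_fraction Fraction of target motif pairs inherited from a
#'   source task (used by [derive_target_task()]).
#' @param label_noise Probability of flipping each label, in `[0, 0.5)`.
#' @param seed Integer seed.
#' @return A `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(n_motif_pairs = 1L, motif_len_tcr = 3L,
                                motif_len_pep = 3L, peptide_len = c(8L, 10L),
                                cdr3_len = c(12L, 18L), shared_fraction = 0,
                                label_noise = 0, seed = 1L) {
  n_motif_pairs <- as.integer(n_motif_pairs)
  motif_len_tcr <- as.integer(motif_len_tcr); motif_len_pep <- as.integer(motif_len_pep)
  if (n_motif_pairs < 1L) stop("n_motif_pairs must be >= 1", call. = FALSE)
  if (motif_len_tcr < 1L || motif_len_pep < 1L)
    stop("motif lengths must be >= 1", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  if (label_noise < 0 || label_noise >= 0.5)
    stop("label_noise must lie in [0, 0.5)", call. = FALSE)
  peptide_len <- as.integer(peptide_len); cdr3_len <- as.integer(cdr3_len)
  stopifnot(length(peptide_len) == 2, length(cdr3_len) == 2,
            peptide_len[1] <= peptide_len[2], cdr3_len[1] <= cdr3_len[2],
            peptide_len[1] >= motif_len_pep, cdr3_len[1] >= motif_len_tcr)
  structure(list(n_motif_pairs = n_motif_pairs, motif_len_tcr = motif_len_tcr,
                 motif_len_pep = motif_len_pep, peptide_len = peptide_len,
                 cdr3_len = cdr3_len, shared_fraction = shared_fraction,
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "synthetic_task_spec")
}

rand_kmer <- function(k) paste(sample(AA_ALPHABET, k, replace = TRUE), collapse = "")

rand_seq <- function(range) {
  len <- if (range[1] == range[2]) range[1] else sample(range[1]:range[2], 1)
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Create a synthetic task from a specification
#'
#' Draws `n_motif_pairs` distinct (TCR motif, peptide motif) pairs uniformly
#' over the alphabet, deterministically from `spec$seed`.
#'
#' @param spec A [synthetic_task_spec].
#' @return A `synthetic_task` with fields `motif_pairs` (data frame with
#'   columns `tcr_motif`, `pep_motif`) and `spec`.
#' @export
make_task <- function(spec) {
  stopifnot(inherits(spec, "synthetic_task_spec"))
  npos <- 20^(spec$motif_len_tcr + spec$motif_len_pep)
  if (spec$n_motif_pairs > npos)
    stop("requested more motif pairs than distinct possibilities", call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  tm <- character(0); pm <- character(0)
  while (length(tm) < spec$n_motif_pairs) {
    a <- rand_kmer(spec$motif_len_tcr); b <- rand_kmer(spec$motif_len_pep)
    if (!any(tm == a & pm == b)) { tm <- c(tm, a); pm <- c(pm, b) }
  }
  structure(list(motif_pairs = data.frame(tcr_motif = tm, pep_motif = pm,
                                          stringsAsFactors = FALSE),
                 spec = spec),
            class = "synthetic_task")
}

#' @export
print.synthetic_task <- function(x, ...) {
  cat(sprintf("<synthetic_task> %d motif pair(s), peptide lengths %d-%d, CDR3 lengths %d-%d, noise %.2f\n",
              nrow(x$motif_pairs), x$spec$peptide_len[1], x$spec$peptide_len[2],
              x$spec$cdr3_len[1], x$spec$cdr3_len[2], x$spec$label_noise))
  invisible(x)
}

#' Does a pair satisfy a task's binding rule?
#'
#' Vectorized exhaustive substring check — the exact ground-truth oracle for
#' synthetic tasks.
#'
#' @param task A `synthetic_task`.
#' @param cdr3b,peptide Character vectors (recycled to equal length).
#' @return Logical vector.
#' @export
task_binds <- function(task, cdr3b, peptide) {
  n <- max(length(cdr3b), length(peptide))
  cdr3b <- rep_len(cdr3b, n); peptide <- rep_len(peptide, n)
  out <- rep(FALSE, n)
  for (i in seq_len(nrow(task$motif_pairs))) {
    out <- out | (grepl(task$motif_pairs$tcr_motif[i], cdr3b, fixed = TRUE) &
                    grepl(task$motif_pairs$pep_motif[i], peptide, fixed = TRUE))
  }
  out
}

#' Derive a related target task from a source task
#'
#' The target inherits `round(shared_fraction * n_motif_pairs)` motif pairs
#' from the source (sampled without replacement) and draws the rest fresh,
#' distinct from all source pairs; the peptide length regime switches to the
#' target range in `spec`.
#'
#' @param source A `synthetic_task`.
#' @param spec A [synthetic_task_spec] for the target (its `shared_fraction`,
#'   lengths, noise and seed apply).
#' @return A `synthetic_task`.
#' @export
derive_target_task <- function(source, spec) {
  stopifnot(inherits(source, "synthetic_task"), inherits(spec, "synthetic_task_spec"))
  n <- spec$n_motif_pairs
  n_inherit <- round(spec$shared_fraction * n)
  if (n_inherit > nrow(source$motif_pairs))
    stop(sprintf("shared_fraction demands %d motif pairs but source has only %d",
                 n_inherit, nrow(source$motif_pairs)), call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  take <- if (n_inherit > 0) sample.int(nrow(source$motif_pairs), n_inherit) else integer(0)
  tm <- source$motif_pairs$tcr_motif[take]
  pm <- source$motif_pairs$pep_motif[take]
  stm <- source$motif_pairs$tcr_motif; spm <- source$motif_pairs$pep_motif
  while (length(tm) < n) {
    a <- rand_kmer(spec$motif_len_tcr); b <- rand_kmer(spec$motif_len_pep)
    if (!any(tm == a & pm == b) && !any(stm == a & spm == b)) {
      tm <- c(tm, a); pm <- c(pm, b)
    }
  }
  structure(list(motif_pairs = data.frame(tcr_motif = tm, pep_motif = pm,
                                          stringsAsFactors = FALSE),
                 spec = spec),
            class = "synthetic_task")
}

implant <- function(s, motif) {
  k <- nchar(motif); n <- nchar(s)
  off <- if (n - k + 1 > 1) sample.int(n - k + 1, 1) else 1L
  paste0(substr(s, 1, off - 1), motif, substr(s, off + k, n))
}

#' Sample labeled pairs from a synthetic task
#'
#' Positives implant a randomly chosen motif pair into random background
#' sequences at random valid offsets; negatives are random sequences
#' rejection-sampled to contain no full motif pair. Each label is then flipped
#' with probability `spec$label_noise` (class counts are exact before noise).
#' Deterministic from `seed`; the returned dataset is shuffled.
#'
#' @param task A `synthetic_task`.
#' @param n_pos,n_neg Numbers of positive and negative pairs (before noise).
#' @param seed Integer seed.
#' @param max_tries Rejection-sampling budget per negative.
#' @return A labeled `binding_dataset` with provenance `"synthetic"`.
#' @export
sample_pairs <- function(task, n_pos, n_neg, seed = 1L, max_tries = 1000L) {
  stopifnot(inherits(task, "synthetic_task"), n_pos >= 0, n_neg >= 0)
  spec <- task$spec
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  nm <- nrow(task$motif_pairs)
  cdr3 <- character(n_pos + n_neg); pep <- character(n_pos + n_neg)
  truth <- c(rep(1, n_pos), rep(0, n_neg))
  for (i in seq_len(n_pos)) {
    mp <- if (nm > 1) sample.int(nm, 1) else 1L
    cdr3[i] <- implant(rand_seq(spec$cdr3_len), task$motif_pairs$tcr_motif[mp])
    pep[i] <- implant(rand_seq(spec$peptide_len), task$motif_pairs$pep_motif[mp])
  }
  for (i in seq_len(n_neg)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a <- rand_seq(spec$cdr3_len); b <- rand_seq(spec$peptide_len)
      if (!task_binds(task, a, b)) { ok <- TRUE; break }
    }
    if (!ok)
      stop("rejection sampling failed to find a negative within ", max_tries,
           " tries; the task spec leaves almost no non-binding pairs", call. = FALSE)
    cdr3[n_pos + i] <- a; pep[n_pos + i] <- b
  }
  label <- truth
  if (spec$label_noise > 0) {
    flip <- stats::runif(length(label)) < spec$label_noise
    label <- ifelse(flip, 1 - label, label)
  }
  ord <- sample.int(length(label))
  binding_dataset(cdr3[ord], pep[ord], label[ord], provenance = "synthetic",
                  validate = FALSE)
}

#' Reference source-abundant / target-scarce benchmark
#'
#' Builds the reference scarcity experiment emulating the CD8-abundant /
#' CD4-scarce structure: a source task with 20 motif pairs in the ~9-mer
#' peptide regime, a target task derived with shared fraction 0.7 in the
#' ~15-mer regime, label noise 0.05 on both, and balanced datasets of sizes
#' source_train 4500, source_valid 500 (about nine times the target volume),
#' target_train 450, target_valid 100, target_test 1000. The target test set
#' is disjoint from target training pairs. Fully reproducible from `seed`.
#'
#' @param seed Integer seed.
#' @param scale Optional multiplier (default 1) shrinking all dataset sizes
#'   proportionally for quick runs; the 9:1 source:target ratio is preserved.
#' @return List of `binding_dataset`s: `source_train`, `source_valid`,
#'   `target_train`, `target_valid`, `target_test`, plus the `source_task` and
#'   `target_task` objects.
#' @export
make_scarcity_benchmark <- function(seed = 1L, scale = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max - 1L, 8L)
  .Random.seed_restore(old)

  sz <- function(n) max(20L, as.integer(round(n * scale)))
  src_spec <- synthetic_task_spec(n_motif_pairs = 20L, peptide_len = c(8L, 10L),
                                  cdr3_len = c(12L, 18L), label_noise = 0.05,
                                  seed = subseeds[1])
  source_task <- make_task(src_spec)
  tgt_spec <- synthetic_task_spec(n_motif_pairs = 20L, peptide_len = c(13L, 17L),
                                  cdr3_len = c(12L, 18L), shared_fraction = 0.7,
                                  label_noise = 0.05, seed = subseeds[2])
  target_task <- derive_target_task(source_task, tgt_spec)

  half <- function(n) as.integer(n / 2)
  n_st <- sz(4500); n_sv <- sz(500); n_tt <- sz(450); n_tv <- sz(100); n_te <- sz(1000)
  source_train <- sample_pairs(source_task, half(n_st), n_st - half(n_st), seed = subseeds[3])
  source_valid <- sample_pairs(source_task, half(n_sv), n_sv - half(n_sv), seed = subseeds[4])
  target_train <- sample_pairs(target_task, half(n_tt), n_tt - half(n_tt), seed = subseeds[5])
  target_valid <- sample_pairs(target_task, half(n_tv), n_tv - half(n_tv), seed = subseeds[6])

  # target test set, kept disjoint from target training pairs
  test_seed <- subseeds[7]
  target_test <- sample_pairs(target_task, half(n_te), n_te - half(n_te), seed = test_seed)
  trkey <- paste(target_train$cdr3b, target_train$peptide)
  for (round_i in 1:20) {
    clash <- paste(target_test$cdr3b, target_test$peptide) %in% trkey
    if (!any(clash)) break
    test_seed <- test_seed + 1001L
    repl <- sample_pairs(target_task, half(n_te), n_te - half(n_te), seed = test_seed)
    target_test <- subset_bd(target_test, which(!clash))
    addkey <- !(paste(repl$cdr3b, repl$peptide) %in%
                  c(trkey, paste(target_test$cdr3b, target_test$peptide)))
    need <- sum(clash)
    add <- subset_bd(repl, which(addkey)[seq_len(min(need, sum(addkey)))])
    target_test <- binding_dataset(c(target_test$cdr3b, add$cdr3b),
                                   c(target_test$peptide, add$peptide),
                                   c(target_test$label, add$label),
                                   provenance = "synthetic", validate = FALSE)
  }

  list(source_train = source_train, source_valid = source_valid,
       target_train = target_train, target_valid = target_valid,
       target_test = target_test,
       source_task = source_task, target_task = target_task)
}

#' Run the transfer-versus-scratch reference experiment for one seed
#'
#' Trains a source-task scorer on the abundant source data, transfers its
#' parameters to initialize a target-task scorer and fine-tunes it on the
#' scarce target data, trains an identical architecture from scratch on the
#' same target data, and evaluates both on the held-out target test set.
#'
#' @param seed Integer seed (controls the benchmark data and all training).
#' @param config A [scorer_config] (default: convolutional family).
#' @param source_tconf,target_tconf [training_config]s for source training and
#'   target fine-tuning/scratch training (seeds are derived from `seed`).
#' @param scale Benchmark size multiplier, passed to
#'   [make_scarcity_benchmark()].
#' @return List with `auc_transfer`, `auc_scratch`, the two trained models and
#'   the benchmark.
#' @export
transfer_experiment <- function(seed = 1L,
                                config = scorer_config("convolutional"),
                                source_tconf = training_config(epochs = 60L, seed = seed),
                                target_tconf = training_config(epochs = 80L, seed = seed + 1L),
                                scale = 1) {
  bench <- make_scarcity_benchmark(seed, scale = scale)
  scheme <- encoding_scheme()
  src <- build_scorer(config, scheme, seed = seed)
  src <- train_scorer(src, bench$source_train, bench$source_valid, source_tconf)
  init <- transfer_parameters(src)
  transferred <- fine_tune(init, bench$target_train, bench$target_valid, target_tconf)
  scratch <- build_scorer(config, scheme, seed = seed + 2L)
  scratch <- train_scorer(scratch, bench$target_train, bench$target_valid, target_tconf)
  y <- bench$target_test$label
  list(auc_transfer = roc_auc(y, predict(transferred, bench$target_test)),
       auc_scratch = roc_auc(y, predict(scratch, bench$target_test)),
       transferred = transferred, scratch = scratch, source_model = src,
       benchmark = bench)
}
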