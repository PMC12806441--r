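test_that("task construction is deterministic with distinct motif pairs", {
  spec <- synthetic_task_spec(n_motif_pairs = 5, seed = 3)
  t1 <- make_task(spec)
  t2 <- make_task(spec)
  expect_identical(t1$motif_pairs, t2$motif_pairs)
  expect_equal(nrow(t1$motif_pairs), 5)
  key <- paste(t1$motif_pairs$tcr_motif, t1$motif_pairs$pep_motif)
  expect_equal(length(unique(key)), 5)
  expect_true(all(nchar(t1$motif_pairs$tcr_motif) == 3))
  expect_error(synthetic_task_spec(motif_len_tcr = 0), ">= 1")
  expect_error(synthetic_task_spec(label_noise = 0.5), "0.5")
})

test_that("noiseless labels equal the substring binding rule exactly", {
  task <- make_task(synthetic_task_spec(n_motif_pairs = 3, seed = 14))
  ds <- sample_pairs(task, 100, 100, seed = 6)
  expect_equal(nrow(ds), 200)
  expect_equal(sum(ds$label), 100)
  truth <- task_binds(task, ds$cdr3b, ds$peptide)
  expect_identical(as.numeric(truth), ds$label)
  # all-negative degenerate dataset
  ds0 <- sample_pairs(task, 0, 30, seed = 7)
  expect_equal(sum(ds0$label), 0)
  # determinism
  expect_identical(as.data.frame(sample_pairs(task, 50, 50, seed = 8)),
                   as.data.frame(sample_pairs(task, 50, 50, seed = 8)))
})

test_that("label noise flips the expected fraction of labels", {
  spec <- synthetic_task_spec(n_motif_pairs = 2, label_noise = 0.1, seed = 5)
  task <- make_task(spec)
  hits <- 0
  for (s in 1:10) {
    ds <- sample_pairs(task, 1000, 1000, seed = 100 + s)
    truth <- as.numeric(task_binds(task, ds$cdr3b, ds$peptide))
    flipped <- mean(ds$label != truth)
    if (flipped >= 0.08 && flipped <= 0.12) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("negative rejection sampling errors when the rule admits no negatives", {
  all_pairs <- expand.grid(tcr_motif = AA_ALPHABET, pep_motif = AA_ALPHABET,
                           stringsAsFactors = FALSE)
  task <- structure(list(motif_pairs = all_pairs,
                         spec = synthetic_task_spec(n_motif_pairs = 400,
                                                    motif_len_tcr = 1,
                                                    motif_len_pep = 1, seed = 1)),
                    class = "synthetic_task")
  expect_error(sample_pairs(task, 0, 5, seed = 1, max_tries = 50),
               "rejection sampling failed")
})

test_that("derived target tasks inherit the stated motif fraction", {
  src <- make_task(synthetic_task_spec(n_motif_pairs = 10, seed = 9))
  key <- function(mp) paste(mp$tcr_motif, mp$pep_motif)

  full <- derive_target_task(src, synthetic_task_spec(
    n_motif_pairs = 10, shared_fraction = 1, peptide_len = c(13, 17), seed = 10))
  expect_setequal(key(full$motif_pairs), key(src$motif_pairs))
  expect_equal(full$spec$peptide_len, c(13L, 17L))

  none <- derive_target_task(src, synthetic_task_spec(
    n_motif_pairs = 10, shared_fraction = 0, peptide_len = c(13, 17), seed = 10))
  expect_length(intersect(key(none$motif_pairs), key(src$motif_pairs)), 0)

  part <- derive_target_task(src, synthetic_task_spec(
    n_motif_pairs = 10, shared_fraction = 0.7, peptide_len = c(13, 17), seed = 10))
  expect_length(intersect(key(part$motif_pairs), key(src$motif_pairs)), 7)

  small <- make_task(synthetic_task_spec(n_motif_pairs = 2, seed = 9))
  expect_error(derive_target_task(small, synthetic_task_spec(
    n_motif_pairs = 10, shared_fraction = 0.7, seed = 1)), "only 2")
})

test_that("the scarcity benchmark reproduces the 9:1 source:target structure", {
  b <- make_scarcity_benchmark(seed = 2, scale = 0.2)
  ratio <- (nrow(b$source_train) + nrow(b$source_valid)) /
    (nrow(b$target_train) + nrow(b$target_valid))
  expect_gt(ratio, 8.5)
  expect_lt(ratio, 9.7)
  # peptide length regimes
  expect_true(all(nchar(b$source_train$peptide) %in% 8:10))
  expect_true(all(nchar(b$target_train$peptide) %in% 13:17))
  expect_true(all(nchar(b$target_test$peptide) %in% 13:17))
  # test set disjoint from target training pairs
  expect_length(intersect(paste(b$target_test$cdr3b, b$target_test$peptide),
                          paste(b$target_train$cdr3b, b$target_train$peptide)), 0)
  # shared motif structure: 14 of 20 motif pairs inherited
  key <- function(mp) paste(mp$tcr_motif, mp$pep_motif)
  expect_length(intersect(key(b$target_task$motif_pairs),
                          key(b$source_task$motif_pairs)), 14)
  # reproducibility
  b2 <- make_scarcity_benchmark(seed = 2, scale = 0.2)
  expect_identical(as.data.frame(b$source_train), as.data.frame(b2$source_train))
  expect_identical(as.data.frame(b$target_test), as.data.frame(b2$target_test))
})

test_that("full-size benchmark dimensions match the reference experiment", {
  b <- make_scarcity_benchmark(seed = 1)
  expect_equal(nrow(b$source_train), 4500)
  expect_equal(nrow(b$source_valid), 500)
  expect_equal(nrow(b$target_train), 450)
  expect_equal(nrow(b$target_valid), 100)
  expect_equal(nrow(b$target_test), 1000)
  expect_equal((4500 + 500) / (450 + 100), 9.09, tolerance = 0.001)
})
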