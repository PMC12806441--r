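test_that("ROC-AUC matches hand-computed cases", {
  expect_equal(roc_auc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0), c(0.5, 0.5)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0, 1, 0), c(0.9, 0.4, 0.6, 0.1, 0.7, 0.3)), 8 / 9)
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "single class")
})

test_that("ROC-AUC equals brute-force Mann-Whitney counting", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), sample(1:3, 1)) # rounding induces ties
    expect_equal(roc_auc(labels, scores), bf_roc_auc(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("PR-AUC follows the average-precision convention", {
  expect_equal(pr_auc(c(1, 0), c(0.9, 0.1)), 1)
  expect_equal(pr_auc(c(0, 1), c(0.9, 0.1)), 0.5)
  # independent oracle: walk the sorted scores accumulating precision mass
  ap_oracle <- function(labels, scores) {
    o <- order(scores, decreasing = TRUE)
    y <- labels[o]; s <- scores[o]
    ap <- 0; tp <- 0; prev_tp <- 0; i <- 1; n <- length(y)
    while (i <= n) {
      j <- i
      while (j < n && s[j + 1] == s[i]) j <- j + 1
      tp <- tp + sum(y[i:j])
      ap <- ap + (tp - prev_tp) / sum(labels) * (tp / j)
      prev_tp <- tp
      i <- j + 1
    }
    ap
  }
  set.seed(6)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)
    expect_equal(pr_auc(labels, scores), ap_oracle(labels, scores), tolerance = 1e-12)
  }
})

test_that("metric reports satisfy the confusion-matrix identities", {
  set.seed(8)
  labels <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
  scores <- pmin(pmax(labels * 0.3 + runif(40) * 0.7, 0), 1)
  m <- compute_metrics(labels, scores, threshold = 0.5)
  cm <- m$confusion
  expect_equal(sum(cm), 40)
  expect_equal(m$accuracy, unname((cm["TP"] + cm["TN"]) / 40))
  expect_equal(m$precision, unname(cm["TP"] / (cm["TP"] + cm["FP"])))
  expect_equal(m$recall, unname(cm["TP"] / (cm["TP"] + cm["FN"])))
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))
  expect_equal(m$roc_auc, bf_roc_auc(labels, scores))
})

subset_pos <- function(pos, pep)
  binding_dataset(pos$cdr3b[pos$peptide == pep], pos$peptide[pos$peptide == pep],
                  rep(1, sum(pos$peptide == pep)), validate = FALSE)

test_that("negative sampling balances classes without positive collisions", {
  set.seed(9)
  pool <- vapply(1:200, function(i) rand_aa(sample(10:16, 1)), "")
  pos <- binding_dataset(sample(pool, 10), rep(c("GILGFVFTL", "NLVPMVATV"), 5),
                         rep(1, 10), validate = FALSE)
  ds <- negative_sample(pos, pool, ratio = 1.0, seed = 4)
  expect_equal(nrow(ds), 20)
  expect_equal(sum(ds$label == 1), 10)
  expect_equal(sum(ds$label == 0), 10)
  poskey <- paste(pos$cdr3b, pos$peptide)
  negkey <- paste(negatives(ds)$cdr3b, negatives(ds)$peptide)
  expect_length(intersect(poskey, negkey), 0)
  # determinism
  expect_identical(as.data.frame(negative_sample(pos, pool, seed = 4)),
                   as.data.frame(ds))
  # ratio scaling
  expect_equal(sum(negative_sample(pos, pool, ratio = 2, seed = 4)$label == 0), 20)
  # exhausted pool names the peptide
  tiny_pool <- unique(pos$cdr3b[pos$peptide == "GILGFVFTL"])
  expect_error(negative_sample(subset_pos(pos, "GILGFVFTL"), tiny_pool, seed = 1),
               "GILGFVFTL")
})

test_that("seen/unseen peptide split partitions validation pairs", {
  val <- binding_dataset(vapply(1:5, function(i) rand_aa(12), ""),
                         c("GILGFVFTL", "GILGFVFTL", "GILGFVFTL", "NLVPMVATV", "NLVPMVATV"),
                         rep(1, 5), validate = FALSE)
  train <- binding_dataset(vapply(1:3, function(i) rand_aa(12), ""),
                           rep("GILGFVFTL", 3), rep(1, 3), validate = FALSE)
  sp <- split_seen_unseen(val, train)
  expect_equal(nrow(sp$shared) + nrow(sp$unique), 5)
  expect_true(all(sp$shared$peptide == "GILGFVFTL"))
  expect_true(all(sp$unique$peptide == "NLVPMVATV"))
  expect_equal(attr(sp, "n_peptides_shared"), 1)
  expect_equal(attr(sp, "n_peptides_unique"), 1)
  # empty training: everything unseen
  empty <- binding_dataset(character(0), character(0), numeric(0))
  sp0 <- split_seen_unseen(val, empty)
  expect_equal(nrow(sp0$shared), 0)
  expect_equal(nrow(sp0$unique), 5)
})

test_that("similarity filter removes near-duplicates and is monotone", {
  train <- binding_dataset(c("CASSLGQETQYF", "CASSIRSSYEQYF"),
                           c("GILGFVFTL", "GILGFVFTL"), c(1, 1))
  val <- binding_dataset(c("CASSLGQETQYF",   # identical to a training CDR3
                           "CASSLGQETQYW",   # distance 1, similarity 11/12
                           "WGGGGGGETWWWGG"),# far from both
                         rep("NLVPMVATV", 3), c(1, 1, 1))
  kept_high <- suppressMessages(similarity_filter(val, train, 1.0))
  expect_false("CASSLGQETQYF" %in% kept_high$cdr3b) # exact duplicate removed
  expect_true("CASSLGQETQYW" %in% kept_high$cdr3b)
  kept_09 <- suppressMessages(similarity_filter(val, train, 0.9))
  expect_equal(kept_09$cdr3b, "WGGGGGGETWWWGG")
  # derived case: closest training CDR3 at distance 3 of length 6 (sim 0.5)
  train6 <- binding_dataset("CAWWWG", rep("GILGFVFTL", 1), 1, validate = FALSE)
  val6 <- binding_dataset("CASSLG", "NLVPMVATV", 1, validate = FALSE)
  expect_equal(dp_edit_distance("CASSLG", "CAWWWG"), 3)
  expect_equal(nrow(suppressMessages(similarity_filter(val6, train6, 0.6))), 1)
  # monotone in the threshold: lowering never retains a removed pair
  set.seed(12)
  for (i in 1:5) {
    tr <- binding_dataset(vapply(1:10, function(j) rand_aa(sample(10:14, 1)), ""),
                          rep("GILGFVFTL", 10), rep(1, 10), validate = FALSE)
    va <- binding_dataset(vapply(1:20, function(j) rand_aa(sample(10:14, 1)), ""),
                          rep("GILGFVFTL", 20), rep(1, 20), validate = FALSE)
    prev <- va$cdr3b
    for (t in c(0.9, 0.7, 0.5, 0.3)) {
      kept <- suppressMessages(similarity_filter(va, tr, t))$cdr3b
      expect_true(all(kept %in% prev))
      prev <- kept
    }
  }
  expect_error(similarity_filter(val, train, 0), "\\(0, 1\\]")
})

test_that("k-mer co-occurrence baseline certifies noiseless tasks", {
  task <- single_motif_task(seed = 33)
  tr <- sample_pairs(task, 150, 150, seed = 1)
  te <- sample_pairs(task, 80, 80, seed = 2)
  expect_gte(roc_auc(te$label, kmer_baseline(tr, te)), 0.95)
})
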