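train_tiny_source <- function(cfg, seed = 1L) {
  task <- single_motif_task()
  tr <- sample_pairs(task, 60, 60, seed = seed)
  va <- sample_pairs(task, 20, 20, seed = seed + 1L)
  train_scorer(build_scorer(cfg, seed = seed), tr, va, quick_tconf(seed = seed))
}

test_that("transfer without head reinit is an exact parameter copy", {
  src <- train_tiny_source(small_conv())
  tgt <- transfer_parameters(src)
  expect_identical(tgt$params, src$params)
  expect_false(tgt$trained)
  expect_match(tgt$provenance, "transfer")
})

test_that("head reinitialization keeps encoders and replaces the head", {
  src <- train_tiny_source(small_lstm())
  tgt <- transfer_parameters(src, reinit_head = TRUE, seed = 99)
  lay <- src$layout
  head_idx <- unlist(lapply(which(lay$group == "head"),
                            function(i) lay$offset[i]:(lay$offset[i] + lay$length[i] - 1)))
  enc_idx <- setdiff(seq_along(src$params), head_idx)
  expect_identical(tgt$params[enc_idx], src$params[enc_idx])
  expect_false(identical(tgt$params[head_idx], src$params[head_idx]))
})

test_that("architecture mismatches and unknown layer names are rejected", {
  src <- train_tiny_source(small_lstm())
  other <- scorer_config("recurrent", embed_dim = 6L, hidden_dim = 32L,
                         head_layers = c(16L, 8L))
  expect_error(transfer_parameters(src, target_config = other),
               "architecture mismatch on 'hidden_dim'")
  expect_error(transfer_parameters(src, frozen_layers = "encoder"),
               "unknown frozen-layer")
  untrained <- build_scorer(small_conv(), seed = 1)
  expect_error(transfer_parameters(untrained), "must be trained")
})

test_that("frozen layers stay bitwise unchanged through fine-tuning", {
  src <- train_tiny_source(small_conv())
  tgt <- transfer_parameters(src, frozen_layers = c("enc_cdr3", "enc_pep"))
  task <- single_motif_task(seed = 21)
  tr <- sample_pairs(task, 40, 40, seed = 5)
  va <- sample_pairs(task, 15, 15, seed = 6)
  ft <- fine_tune(tgt, tr, va, quick_tconf(seed = 2))
  lay <- src$layout
  frozen_idx <- unlist(lapply(which(lay$group %in% c("enc_cdr3", "enc_pep")),
                              function(i) lay$offset[i]:(lay$offset[i] + lay$length[i] - 1)))
  expect_identical(ft$params[frozen_idx], src$params[frozen_idx])
  expect_false(identical(ft$params[-frozen_idx], src$params[-frozen_idx]))

  empty <- binding_dataset(character(0), character(0), numeric(0))
  expect_error(fine_tune(tgt, empty, va, quick_tconf()), "empty")
})

test_that("ensemble scores are means bounded by member scores", {
  m1 <- as_trained(build_scorer(small_conv(), seed = 1))
  m2 <- as_trained(build_scorer(small_conv(), seed = 2))
  task <- single_motif_task()
  ds <- sample_pairs(task, 30, 30, seed = 4)
  p1 <- predict(m1, ds); p2 <- predict(m2, ds)

  avg <- ensemble_scorer(list(m1, m2), "avg")
  pa <- predict(avg, ds)
  expect_identical(pa, (p1 + p2) / 2)
  expect_true(all(pa >= pmin(p1, p2) & pa <= pmax(p1, p2)))
  expect_identical(ensemble_predict(avg, ds), pa)

  sub <- ensemble_scorer(list(m1, m2), "sub", sub_weights = c(1, 0))
  expect_equal(predict(sub, ds), p1)
  sub37 <- ensemble_scorer(list(m1, m2), "sub", sub_weights = c(0.3, 0.7))
  expect_equal(predict(sub37, ds), 0.3 * p1 + 0.7 * p2)

  # identical members: ensemble equals the member in both modes
  same <- ensemble_scorer(list(m1, m1), "avg")
  expect_equal(predict(same, ds), p1)

  expect_error(ensemble_scorer(list(m1), "avg"), "at least 2")
  expect_error(ensemble_scorer(list(m1, m2), "sub"), "requires sub_weights")
  expect_error(ensemble_scorer(list(m1, m2), "sub", sub_weights = c(0.7, 0.7)),
               "summing to 1")
})

test_that("sub-ensemble weights maximize calibration AUC with uniform tie-break", {
  task <- single_motif_task()
  calib <- sample_pairs(task, 25, 25, seed = 10)
  good <- train_tiny_source(small_conv(), seed = 3) # near-perfect on this task
  noise <- as_trained(build_scorer(small_conv(), seed = 77)) # untrained, uninformative
  w <- fit_sub_ensemble_weights(list(good, noise), calib, step = 0.01)
  expect_equal(sum(w), 1)
  expect_gt(w[1], 0.5)

  # oracle: exhaustive grid search re-implemented independently
  sg <- predict(good, calib); sn <- predict(noise, calib)
  grid <- seq(0, 1, by = 0.01)
  aucs <- vapply(grid, function(a) roc_auc(calib$label, a * sg + (1 - a) * sn), 0)
  best <- max(aucs)
  expect_equal(roc_auc(calib$label, w[1] * sg + w[2] * sn), best)
  # among maximizers, the chosen weight is the one closest to uniform
  maxers <- grid[abs(aucs - best) <= 1e-12]
  expect_equal(w[1], maxers[which.min(abs(maxers - 0.5))])

  # identical members tie everywhere -> uniform weights
  w2 <- fit_sub_ensemble_weights(list(good, good), calib)
  expect_equal(w2, c(0.5, 0.5))

  empty <- binding_dataset(character(0), character(0), numeric(0))
  expect_error(fit_sub_ensemble_weights(list(good, noise), empty), "empty")
  onecls <- binding_dataset(calib$cdr3b, calib$peptide, rep(1, nrow(calib)))
  expect_error(fit_sub_ensemble_weights(list(good, noise), onecls), "single class")
})

test_that("transfer learning helps on a scarce target task (small replicate)", {
  r <- transfer_experiment(seed = 42, config = small_conv(),
                           source_tconf = training_config(epochs = 20, seed = 42),
                           target_tconf = training_config(epochs = 30, seed = 43),
                           scale = 0.2)
  expect_true(is.finite(r$auc_transfer) && is.finite(r$auc_scratch))
  expect_true(r$auc_transfer > 0.5) # transferred model must beat chance
})
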