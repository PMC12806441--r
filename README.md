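# tcrbind

Predicting which T cell receptors (TCRs) recognize which peptide epitopes is a
central problem in immunology: it underpins neoantigen-directed immunotherapy,
vaccine design and TCR-T engineering. For CD8⁺ T cells (MHC class I, ~9-mer
peptides) labeled TCR–peptide binding data are relatively abundant; for CD4⁺ T
cells (MHC class II, ~15-mer peptides) they are roughly nine times scarcer,
which cripples models trained on CD4 data alone.

`tcrbind` is an R package for CDR3β–peptide binding prediction built around
the transfer-learning recipe for exactly this data-scarcity regime:

1. **Two trainable scorer families** mapping a (CDR3β, peptide) pair to a
   binding probability: a *recurrent* family (per-sequence LSTM encoders over
   embedded residues, final states concatenated into a fully connected head
   with a sigmoid output) and a *convolutional* family (per-sequence 1-D
   convolutions over one-hot matrices, ReLU + global max pooling per filter
   size, same head). The numerical core is compiled (Rcpp/RcppArmadillo);
   training is mini-batch Adam on binary cross-entropy
   `L = -mean(y log p + (1-y) log(1-p))` with early stopping on validation
   ROC-AUC, and is bit-reproducible from a seed.
2. **Parameter transfer**: a model trained on the abundant source task
   initializes the target-task model (`transfer_parameters()`), optionally
   reinitializing the head or freezing layer groups, followed by fine-tuning
   (`fine_tune()`) on the scarce target data.
3. **Ensembling**: `ensemble_scorer(..., "avg")` averages member
   probabilities (the headline combiner); `"sub"` is a calibration-weighted
   mean with weights fitted by grid search on the simplex.
4. **Percentile binding rank**: for a query pair, every TCR of a background
   repertoire (canonically 1000) is scored against the same peptide and the
   query's rank is `(#above + 0.5·#tied) / N` — rank ≤ 0.05 is called strong
   binding, ≤ 0.1 weak. `scan_repertoire()` flags reactive TCR×peptide
   combinations at a score threshold (default 0.54) and `search_neighbors()`
   finds database pairs within a Levenshtein edit distance of a query.
5. **Evaluation utilities**: ROC-AUC (Mann–Whitney identity), PR-AUC (average
   precision), confusion metrics, negative sampling by shuffling TCRs against
   peptides they are not known to bind, seen/unseen-peptide partitioning, and
   similarity-controlled validation filtering
   (`similarity = 1 − d/max(len)` on CDR3β by default).
6. **A synthetic task generator** (`make_task()`, `sample_pairs()`,
   `make_scarcity_benchmark()`): latent (TCR-motif, peptide-motif) pairs label
   generated sequences through an exact substring rule, so every mechanism —
   learnability, transfer lift, ensembling, ranks — is verifiable at desk
   scale against a perfect oracle.

## Worked example

```r
library(tcrbind)

# a small motif-governed task with exact ground truth
task <- make_task(synthetic_task_spec(n_motif_pairs = 1, seed = 11))
train <- sample_pairs(task, 500, 500, seed = 1)
valid <- sample_pairs(task, 150, 150, seed = 2)
test  <- sample_pairs(task, 150, 150, seed = 3)

cnn <- build_scorer(scorer_config("convolutional"), seed = 1)
cnn <- train_scorer(cnn, train, valid, training_config(epochs = 40, seed = 1))
lstm <- build_scorer(scorer_config("recurrent"), seed = 1)
lstm <- train_scorer(lstm, train, valid, training_config(epochs = 40, seed = 1))

ens <- ensemble_scorer(list(cnn, lstm), mode = "avg")
compute_metrics(test$label, predict(ens, test))
#> <metrics_report> ROC-AUC 0.9991  PR-AUC 0.9991  acc 0.9800  P 0.974  R 0.987  F1 0.980 (thr 0.50)
#>   confusion: TP 148  FP 4  TN 146  FN 2

bg <- background_repertoire(
  vapply(1:1000, function(i)
    paste(sample(AA_ALPHABET, sample(12:18, 1), replace = TRUE), collapse = ""), ""))
binder <- positives(test)[1, ]
compute_rank(binder, ens, bg)
#> <rank_result> score 0.8845, rank 0.0170 vs 1000 background TCRs -> strong binding
```

The ensemble separates true binders from non-binders almost perfectly on the
held-out pairs (ROC-AUC 0.999, 294/300 correct hard calls at threshold 0.5),
and a true binder outranks 98.3% of the 1000-TCR background, well inside the
strong-binding band.

The transfer workflow is one call per step:

```r
bench <- make_scarcity_benchmark(seed = 1)  # 5000 source pairs vs 550 target pairs
src  <- train_scorer(build_scorer(scorer_config("convolutional"), seed = 1),
                     bench$source_train, bench$source_valid, training_config(seed = 1))
tgt  <- fine_tune(transfer_parameters(src), bench$target_train, bench$target_valid,
                  training_config(seed = 2))
```

or, from a shell, via the bundled CLI (installed under `exec/`):

```sh
tcrbind simulate --preset scarcity --seed 7 --outdir data/
tcrbind train --pairs data/source_train.csv --valid data/source_valid.csv \
              --family cnn --seed 3 --out cd8.ckpt
tcrbind transfer --source cd8.ckpt --target-train data/target_train.csv \
                 --target-valid data/target_valid.csv --seed 4 --out cd4.ckpt
tcrbind rank --pair "CASSLGQETQYF,GILGFVFTLTV" --model cd4.ckpt --background bg.txt
```

Input pairs are plain CSV with columns `cdr3b,peptide[,label]` (common header
aliases accepted); repertoires are one sequence per line. A tiny example
lives in `inst/extdata/`.

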