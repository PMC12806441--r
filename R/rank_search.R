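#' Percentile binding rank against a background repertoire
#'
#' Scores the query pair, scores every background TCR against the query's
#' peptide (TCR varies, peptide fixed), and reports the fraction of the
#' background outscoring the query with mid-rank handling of ties:
#' `rank = (#above + 0.5 * #tied) / background_size`. Smaller values indicate
#' stronger binding. A rank within 0.05 is called strong binding, within 0.1
#' weak binding, otherwise non-binding (inclusive thresholds). The mid-rank
#' tie rule makes the rank the complement of a Mann-Whitney placement, so it
#' is exactly antitone in the query score.
#'
#' @param query A one-row `binding_dataset` (or list with `cdr3b`, `peptide`).
#' @param scorer A trained `tcr_scorer` or `tcr_ensemble`.
#' @param background A [background_repertoire] (default size in the field is
#'   1000 TCRs).
#' @param strong_cut,weak_cut Category thresholds (defaults 0.05 and 0.1).
#' @param background_size Optional subsample size; when smaller than the
#'   repertoire, `seed` selects a reproducible subsample.
#' @param seed Seed for the optional subsample.
#' @return A `rank_result`: `score`, `rank`, `category`
#'   (`strong`/`weak`/`non`), `background_size`.
#' @export
compute_rank <- function(query, scorer, background, strong_cut = 0.05,
                         weak_cut = 0.1, background_size = NULL, seed = 1L) {
  stopifnot(inherits(background, "background_repertoire"))
  bg <- as.character(background)
  if (!length(bg)) stop("background repertoire is empty", call. = FALSE)
  if (!is.null(background_size) && background_size < length(bg)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    bg <- bg[sample.int(length(bg), background_size)]
  }
  qd <- binding_dataset(query$cdr3b[1], query$peptide[1], validate = FALSE)
  s <- predict(scorer, qd)
  bgd <- binding_dataset(bg, rep(query$peptide[1], length(bg)), validate = FALSE)
  bs <- predict(scorer, bgd)
  rk <- (sum(bs > s) + 0.5 * sum(bs == s)) / length(bs)
  category <- if (rk <= strong_cut) "strong" else if (rk <= weak_cut) "weak" else "non"
  structure(list(score = s, rank = rk, category = category,
                 background_size = length(bs)),
            class = "rank_result")
}

#' @export
print.rank_result <- function(x, ...) {
  cat(sprintf("<rank_result> score %.4f, rank %.4f vs %d background TCRs -> %s binding\n",
              x$score, x$rank, x$background_size, x$category))
  invisible(x)
}

#' Scan a TCR repertoire against candidate peptides
#'
#' Scores every TCR x peptide combination and returns those at or above the
#' reactivity score threshold (default 0.54), sorted by descending score with
#' ties kept in input order (TCRs outer, peptides inner).
#'
#' @param tcrs,peptides Nonempty character vectors.
#' @param scorer A trained `tcr_scorer` or `tcr_ensemble`.
#' @param score_threshold Reactivity threshold (default 0.54).
#' @return Data frame with columns `cdr3b`, `peptide`, `score`. The numbers of
#'   combinations scored and retained are reported via `message()`.
#' @export
scan_repertoire <- function(tcrs, peptides, scorer, score_threshold = 0.54) {
  if (!length(tcrs)) stop("empty TCR list", call. = FALSE)
  if (!length(peptides)) stop("empty peptide list", call. = FALSE)
  tcrs <- validate_sequence(tcrs, "cdr3")
  peptides <- validate_sequence(peptides, "peptide")
  grid <- data.frame(cdr3b = rep(tcrs, each = length(peptides)),
                     peptide = rep(peptides, times = length(tcrs)),
                     stringsAsFactors = FALSE)
  ds <- binding_dataset(grid$cdr3b, grid$peptide, validate = FALSE)
  sc <- predict(scorer, ds)
  keep <- which(sc >= score_threshold)
  message(sprintf("scan_repertoire: scored %d combinations, %d reactive at threshold %.2f",
                  nrow(grid), length(keep), score_threshold))
  ord <- keep[order(-sc[keep], keep)]
  data.frame(cdr3b = grid$cdr3b[ord], peptide = grid$peptide[ord], score = sc[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Levenshtein edit distance between amino-acid sequences
#'
#' Unit-cost insertion, deletion and substitution distance (dynamic
#' programming). Vectorized over `a` and `b` (recycled).
#'
#' @param a,b Character vectors of valid amino-acid sequences.
#' @return Nonnegative integer vector of distances.
#' @export
edit_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", c(a, b))
  if (any(!ok))
    stop("invalid amino-acid sequence: ", c(a, b)[which(!ok)[1]], call. = FALSE)
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  as.integer(diag(utils::adist(a, b))[seq_len(n)])
}

#' Search a database for pairs within an edit distance of a query
#'
#' Returns database pairs whose CDR3beta is within `max_dist_cdr3` and whose
#' peptide is within `max_dist_peptide` (Levenshtein) of the query, sorted by
#' the summed distance with ties kept in database order.
#'
#' @param query A one-row `binding_dataset` (or list with `cdr3b`, `peptide`).
#' @param database A nonempty `binding_dataset`.
#' @param max_dist_cdr3,max_dist_peptide Nonnegative integer bounds.
#' @return The matching database rows plus `dist_cdr3`, `dist_peptide` and
#'   `dist_total` columns.
#' @export
search_neighbors <- function(query, database, max_dist_cdr3, max_dist_peptide) {
  stopifnot(inherits(database, "binding_dataset"))
  if (!nrow(database)) stop("database is empty", call. = FALSE)
  if (max_dist_cdr3 < 0 || max_dist_peptide < 0)
    stop("distance bounds must be nonnegative", call. = FALSE)
  dc <- as.integer(utils::adist(query$cdr3b[1], database$cdr3b))
  dp <- as.integer(utils::adist(query$peptide[1], database$peptide))
  keep <- which(dc <= max_dist_cdr3 & dp <= max_dist_peptide)
  ord <- keep[order(dc[keep] + dp[keep], keep)]
  out <- as.data.frame(database)[ord, , drop = FALSE]
  out$dist_cdr3 <- dc[ord]
  out$dist_peptide <- dp[ord]
  out$dist_total <- dc[ord] + dp[ord]
  rownames(out) <- NULL
  out
}
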