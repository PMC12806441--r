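# ranks use a mock scorer mapping CDR3 sequences to fixed scores, so every
# comparison against the background is fully controlled

table_scorer <- function(tab) mock_scorer(function(nd) unname(tab[nd$cdr3b]))

rand_bg <- function(n, seed) {
  set.seed(seed)
  background_repertoire(vapply(1:n, function(i) rand_aa(sample(8:16, 1)), ""))
}

test_that("rank hits the extremes and applies the strong/weak thresholds", {
  bg <- rand_bg(20, 1)
  query <- list(cdr3b = "CASSLGQETQYF", peptide = "GILGFVFTL")
  tab <- setNames(rep(0.5, 20), as.character(bg))
  tab[query$cdr3b] <- 0.99
  r <- compute_rank(query, table_scorer(tab), bg)
  expect_equal(r$rank, 0)
  expect_equal(r$category, "strong")
  expect_equal(r$background_size, 20)

  tab[query$cdr3b] <- 0.01
  r <- compute_rank(query, table_scorer(tab), bg)
  expect_equal(r$rank, 1)
  expect_equal(r$category, "non")
})

test_that("ties get mid-rank credit: 1 above + 1 tied of 10 gives 0.15", {
  bg <- rand_bg(10, 2)
  query <- list(cdr3b = "CASSLGQETQYF", peptide = "GILGFVFTL")
  tab <- setNames(seq(0.1, 0.46, length.out = 10), as.character(bg))
  tab[1] <- 0.9   # one background TCR above the query
  tab[2] <- 0.6   # one tied with the query
  tab[query$cdr3b] <- 0.6
  r <- compute_rank(query, table_scorer(tab), bg)
  expect_equal(r$rank, (1 + 0.5) / 10)
  expect_equal(r$category, "non")
})

test_that("category boundaries are inclusive at 0.05 and 0.1", {
  query <- list(cdr3b = "CASSLGQETQYF", peptide = "GILGFVFTL")
  mk <- function(n_above, n) {
    set.seed(100 + n_above)
    bg <- rand_bg(n, 100 + n_above)
    tab <- setNames(c(rep(0.9, n_above), rep(0.1, n - n_above)), as.character(bg))
    tab[query$cdr3b] <- 0.5
    compute_rank(query, table_scorer(tab), bg)
  }
  expect_equal(mk(5, 100)$category, "strong")  # rank exactly 0.05
  expect_equal(mk(6, 100)$category, "weak")    # 0.06
  expect_equal(mk(10, 100)$category, "weak")   # exactly 0.1
  expect_equal(mk(11, 100)$category, "non")    # 0.11
})

test_that("rank is antitone in the query score over randomized backgrounds", {
  query_lo <- list(cdr3b = "CASSAAAAGELF", peptide = "GILGFVFTL")
  query_hi <- list(cdr3b = "CASSTTTTGELF", peptide = "GILGFVFTL")
  for (i in 1:100) {
    bg <- rand_bg(25, 1000 + i)
    set.seed(2000 + i)
    tab <- setNames(round(runif(25), 2), as.character(bg)) # rounding forces ties
    s <- sort(round(runif(2), 2))
    tab[query_lo$cdr3b] <- s[1]
    tab[query_hi$cdr3b] <- s[2]
    r_lo <- compute_rank(query_lo, table_scorer(tab), bg)
    r_hi <- compute_rank(query_hi, table_scorer(tab), bg)
    expect_true(r_hi$rank <= r_lo$rank)
    expect_true(r_lo$rank >= 0 && r_lo$rank <= 1)
  }
})

test_that("repertoire scan scores the full cartesian grid and sorts by score", {
  tcrs <- c("CASSLGQETQYF", "CASSIRSSYEQYF", "CASRPGLAGGRF")
  peps <- c("GILGFVFTL", "NLVPMVATV")
  counter <- new.env(); counter$n <- 0
  sc <- mock_scorer(function(nd) {
    counter$n <- counter$n + nrow(nd)
    (seq_len(nrow(nd)) %% 4) / 4 # scores 0.25 0.5 0.75 0 ... with ties
  })
  res <- suppressMessages(scan_repertoire(tcrs, peps, sc, score_threshold = 0))
  expect_equal(counter$n, 6)
  expect_equal(nrow(res), 6)
  expect_true(all(diff(res$score) <= 0))

  res54 <- suppressMessages(scan_repertoire(tcrs, peps, sc, score_threshold = 0.54))
  expect_true(all(res54$score >= 0.54))
  expect_equal(nrow(suppressMessages(
    scan_repertoire(tcrs, peps, sc, score_threshold = 1.0))), 0)
  expect_error(scan_repertoire(character(0), peps, sc), "empty")
})

test_that("edit distance matches hand cases and the DP oracle", {
  expect_equal(edit_distance("CASSLG", "CASSLG"), 0L)
  expect_equal(edit_distance("CASS", "CAST"), 1L)
  expect_equal(edit_distance("CA", "CAGG"), 2L)
  expect_error(edit_distance("CAX1", "CASS"), "invalid")
  set.seed(31)
  for (i in 1:200) {
    a <- rand_aa(sample(2:15, 1)); b <- rand_aa(sample(2:15, 1))
    expect_equal(edit_distance(a, b), dp_edit_distance(a, b))
  }
})

test_that("neighbor search equals brute-force filter-and-sort", {
  set.seed(17)
  db <- binding_dataset(vapply(1:300, function(i) rand_aa(sample(8:14, 1)), ""),
                        vapply(1:300, function(i) rand_aa(sample(8:12, 1)), ""),
                        validate = FALSE)
  for (rep in 1:10) {
    q <- list(cdr3b = db$cdr3b[sample(300, 1)], peptide = rand_aa(9))
    got <- search_neighbors(q, db, 3, 4)
    dc <- vapply(db$cdr3b, function(s) dp_edit_distance(q$cdr3b, s), 0)
    dp <- vapply(db$peptide, function(s) dp_edit_distance(q$peptide, s), 0)
    keep <- which(dc <= 3 & dp <= 4)
    ord <- keep[order(dc[keep] + dp[keep], keep)]
    expect_equal(got$cdr3b, db$cdr3b[ord])
    expect_equal(got$dist_total, unname(dc[ord] + dp[ord]))
  }
  # exact-match bounds
  q <- list(cdr3b = db$cdr3b[5], peptide = db$peptide[5])
  hit <- search_neighbors(q, db, 0, 0)
  expect_true(all(hit$cdr3b == q$cdr3b & hit$peptide == q$peptide))
  miss <- search_neighbors(list(cdr3b = strrep("W", 12), peptide = strrep("W", 9)),
                           db, 0, 0)
  expect_equal(nrow(miss), 0)
  expect_error(search_neighbors(q, db, -1, 0), "nonnegative")
})
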