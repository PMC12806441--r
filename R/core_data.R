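#' @useDynLib tcrbind, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif rbinom setNames
#' @importFrom utils read.csv write.csv adist head
NULL

#' The 20-letter standard amino-acid alphabet, alphabetical order
#'
#' Index 0 is reserved for padding throughout the package; residues map to
#' indices 1..20 in this order.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# default length bounds per sequence role; wide enough for both the ~9-mer
# (MHC class I) and ~15-mer (MHC class II) peptide regimes
ROLE_BOUNDS <- list(cdr3 = c(6L, 30L), peptide = c(7L, 30L))

#' Validate and normalize an amino-acid sequence
#'
#' Uppercases the input and checks it against the 20-letter standard alphabet
#' and the length bounds for its role (CDR3beta: 6-30 residues, peptide: 7-30
#' by default). Offending characters are reported with their positions.
#'
#' @param raw Character scalar (or vector) to validate.
#' @param role One of `"cdr3"`, `"peptide"`; selects the length bounds.
#' @param bounds Integer length-2 vector overriding the role's default
#'   `c(min, max)` length bounds.
#' @return The validated, uppercase sequence(s), invisibly classed as plain
#'   character. Idempotent: validating the output returns an equal value.
#' @examples
#' validate_sequence("cassirss", "cdr3")
#' @export
validate_sequence <- function(raw, role = c("cdr3", "peptide"), bounds = NULL) {
  role <- match.arg(role)
  if (is.null(bounds)) bounds <- ROLE_BOUNDS[[role]]
  if (!is.character(raw)) stop("sequence must be character, got ", class(raw)[1], call. = FALSE)
  if (any(is.na(raw))) stop("sequence is NA", call. = FALSE)
  s <- toupper(raw)
  if (any(!nzchar(s))) stop("empty ", role, " sequence", call. = FALSE)
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", s)
  if (any(bad)) {
    first <- s[which(bad)[1]]
    chars <- strsplit(first, "")[[1]]
    off <- which(!chars %in% AA_ALPHABET)
    stop(sprintf("invalid %s sequence '%s': character%s %s at position%s %s",
                 role, first, if (length(off) > 1) "s" else "",
                 paste(sprintf("'%s'", chars[off]), collapse = ", "),
                 if (length(off) > 1) "s" else "",
                 paste(off, collapse = ", ")), call. = FALSE)
  }
  n <- nchar(s)
  if (any(n < bounds[1] | n > bounds[2])) {
    i <- which(n < bounds[1] | n > bounds[2])[1]
    stop(sprintf("%s sequence '%s' has length %d, outside allowed [%d, %d]",
                 role, s[i], n[i], bounds[1], bounds[2]), call. = FALSE)
  }
  s
}

#' Construct a binding dataset
#'
#' A `binding_dataset` is a data frame with columns `cdr3b`, `peptide` and
#' (optionally) a binary `label` (1 = binds), carrying a free-text
#' `provenance` attribute. It is the atomic container for training,
#' validation and batch-prediction records.
#'
#' @param cdr3b,peptide Character vectors of equal length.
#' @param label Optional numeric/integer vector of 0/1 (NA allowed for
#'   unlabeled rows); omit for prediction-only datasets.
#' @param provenance Free-text tag, e.g. `"source"`, `"target"`, `"synthetic"`.
#' @param validate Validate sequences (default `TRUE`).
#' @return A `binding_dataset`.
#' @export
binding_dataset <- function(cdr3b, peptide, label = NULL, provenance = "unspecified",
                            validate = TRUE) {
  if (length(cdr3b) != length(peptide))
    stop("cdr3b and peptide must have equal length", call. = FALSE)
  if (validate && length(cdr3b)) {
    cdr3b <- validate_sequence(cdr3b, "cdr3")
    peptide <- validate_sequence(peptide, "peptide")
  } else {
    cdr3b <- toupper(as.character(cdr3b))
    peptide <- toupper(as.character(peptide))
  }
  df <- data.frame(cdr3b = as.character(cdr3b), peptide = as.character(peptide),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) {
    lab <- suppressWarnings(as.numeric(label))
    bad <- !is.na(lab) & !(lab %in% c(0, 1))
    if (any(is.na(lab) & !is.na(label)) || any(bad))
      stop("labels must be 0 or 1 (or NA); offending rows: ",
           paste(head(which(bad | (is.na(lab) & !is.na(label))), 5), collapse = ", "),
           call. = FALSE)
    if (length(lab) != nrow(df) && nrow(df) > 0)
      stop("label length does not match number of pairs", call. = FALSE)
    df$label <- lab
  }
  structure(df, class = c("binding_dataset", "data.frame"), provenance = provenance)
}

#' @export
print.binding_dataset <- function(x, ...) {
  cat(sprintf("<binding_dataset> %d pairs (provenance: %s)%s\n",
              nrow(x), attr(x, "provenance") %||% "unspecified",
              if (!is.null(x$label)) sprintf(", %d positive / %d negative",
                                             sum(x$label == 1, na.rm = TRUE),
                                             sum(x$label == 0, na.rm = TRUE)) else ""))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Labeled subsets of a binding dataset
#'
#' `positives()` and `negatives()` partition the labeled pairs of a dataset.
#' @param dataset A `binding_dataset` with a `label` column.
#' @return A `binding_dataset` restricted to label 1 (or 0).
#' @export
positives <- function(dataset) {
  stopifnot(inherits(dataset, "binding_dataset"))
  if (is.null(dataset$label)) stop("dataset has no labels", call. = FALSE)
  subset_bd(dataset, which(dataset$label == 1))
}

#' @rdname positives
#' @export
negatives <- function(dataset) {
  stopifnot(inherits(dataset, "binding_dataset"))
  if (is.null(dataset$label)) stop("dataset has no labels", call. = FALSE)
  subset_bd(dataset, which(dataset$label == 0))
}

# row subset preserving class + provenance
subset_bd <- function(dataset, idx) {
  out <- as.data.frame(dataset)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("binding_dataset", "data.frame"),
            provenance = attr(dataset, "provenance"))
}

# accepted header aliases (lowercased) -> canonical column
COLUMN_ALIASES <- list(
  cdr3b = c("cdr3b", "cdr3", "cdr3.beta", "cdr3_beta", "tcr", "cdr3b_aa"),
  peptide = c("peptide", "epitope", "antigen", "pep"),
  label = c("label", "binder", "bind", "y")
)

#' Read a CSV of CDR3beta/peptide pairs
#'
#' Expects a header with columns `cdr3b`, `peptide` and, when
#' `require_label = TRUE`, `label`; common aliases (`CDR3`, `Peptide`,
#' `Label`, ...) are accepted. Every row is validated; exact duplicate
#' `(cdr3b, peptide, label)` rows are dropped keeping the first occurrence.
#' The same pair carrying both labels 0 and 1 is a curation error and is
#' rejected.
#'
#' @param path CSV file path (RFC-4180 style, UTF-8, header required).
#' @param require_label Require and parse a binary label column.
#' @param permissive Drop invalid rows with a message instead of erroring.
#' @param provenance Tag stored on the returned dataset.
#' @return A `binding_dataset`. The numbers of rows read and duplicates
#'   dropped are reported via `message()`.
#' @export
read_pairs_csv <- function(path, require_label = FALSE, permissive = FALSE,
                           provenance = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         check.names = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  for (canon in names(COLUMN_ALIASES)) {
    hit <- which(names(raw) %in% COLUMN_ALIASES[[canon]])
    if (length(hit)) names(raw)[hit[1]] <- canon
  }
  for (col in c("cdr3b", "peptide", if (require_label) "label"))
    if (!col %in% names(raw)) stop("missing column: ", col, call. = FALSE)

  has_label <- "label" %in% names(raw)
  lab <- NULL
  if (has_label) {
    lab <- suppressWarnings(as.numeric(raw$label))
    badlab <- which(is.na(lab) | !(lab %in% c(0, 1)))
    if (length(badlab)) {
      if (!permissive)
        stop("unparseable label (must be 0/1) in row(s): ",
             paste(head(badlab, 10), collapse = ", "), call. = FALSE)
      message("dropping ", length(badlab), " row(s) with unparseable labels")
      raw <- raw[-badlab, , drop = FALSE]; lab <- lab[-badlab]
    }
  }

  ok_c <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", toupper(raw$cdr3b)) &
    nchar(raw$cdr3b) >= ROLE_BOUNDS$cdr3[1] & nchar(raw$cdr3b) <= ROLE_BOUNDS$cdr3[2]
  ok_p <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", toupper(raw$peptide)) &
    nchar(raw$peptide) >= ROLE_BOUNDS$peptide[1] & nchar(raw$peptide) <= ROLE_BOUNDS$peptide[2]
  bad <- which(!(ok_c & ok_p))
  if (length(bad)) {
    if (!permissive)
      stop("invalid sequence(s) in row(s): ", paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10) else "",
           call. = FALSE)
    message("dropping ", length(bad), " row(s) failing sequence validation")
    raw <- raw[-bad, , drop = FALSE]
    if (has_label) lab <- lab[-bad]
  }

  cdr3b <- toupper(raw$cdr3b); peptide <- toupper(raw$peptide)
  key <- paste(cdr3b, peptide, if (has_label) lab else "", sep = "\r")
  dup <- duplicated(key)
  n_dropped <- sum(dup)
  if (n_dropped) {
    cdr3b <- cdr3b[!dup]; peptide <- peptide[!dup]
    if (has_label) lab <- lab[!dup]
  }
  if (has_label) {
    pairkey <- paste(cdr3b, peptide, sep = "\r")
    confl <- unique(pairkey[duplicated(pairkey)])
    if (length(confl)) {
      ex <- utils::head(sub("\r", " / ", confl), 5)
      stop("conflicting labels (same pair labeled 0 and 1) for: ",
           paste(ex, collapse = "; "),
           if (length(confl) > 5) sprintf(" (and %d more)", length(confl) - 5) else "",
           call. = FALSE)
    }
  }
  message(sprintf("read %d row(s) from %s; dropped %d exact duplicate(s)",
                  nrow(raw), path, n_dropped))
  binding_dataset(cdr3b, peptide, label = if (has_label) lab else NULL,
                  provenance = provenance, validate = FALSE)
}

#' Write predictions to CSV
#'
#' Writes columns `cdr3b`, `peptide`, `score` and, when ranks are supplied,
#' `rank` and `category`, preserving the input row order.
#'
#' @param pairs A `binding_dataset`.
#' @param scores Numeric vector of per-pair probabilities in `[0, 1]`, one per
#'   pair.
#' @param path Output CSV path.
#' @param ranks Optional list of [rank_result] objects (or a data frame with
#'   columns `rank`, `category`), one per pair.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(pairs, scores, path, ranks = NULL) {
  stopifnot(inherits(pairs, "binding_dataset"))
  if (length(scores) != nrow(pairs))
    stop("length mismatch: ", nrow(pairs), " pairs but ", length(scores), " scores",
         call. = FALSE)
  if (length(scores) && (any(!is.finite(scores)) || any(scores < 0 | scores > 1)))
    stop("scores must lie in [0, 1]", call. = FALSE)
  out <- data.frame(cdr3b = pairs$cdr3b, peptide = pairs$peptide, score = scores,
                    stringsAsFactors = FALSE)
  if (!is.null(ranks)) {
    if (is.data.frame(ranks)) {
      rk <- ranks$rank; cat_ <- ranks$category
    } else {
      rk <- vapply(ranks, function(r) r$rank, numeric(1))
      cat_ <- vapply(ranks, function(r) r$category, character(1))
    }
    if (length(rk) != nrow(pairs))
      stop("length mismatch between pairs and ranks", call. = FALSE)
    out$rank <- rk; out$category <- cat_
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a pairs dataset to CSV
#'
#' Inverse of [read_pairs_csv()]: columns `cdr3b`, `peptide` and, when
#' present, `label`; reading the file back reproduces the same multiset of
#' pairs.
#'
#' @param dataset A `binding_dataset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pairs_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "binding_dataset"))
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a background TCR repertoire
#'
#' Accepts one sequence per line (plain text) or a one-column CSV with an
#' optional header.
#'
#' @param path File path.
#' @return A `background_repertoire`: a validated character vector of CDR3beta
#'   sequences with a `size` attribute.
#' @export
read_repertoire <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty repertoire file: ", path, call. = FALSE)
  # tolerate a header line (any alias of cdr3b, or a non-sequence token)
  first <- tolower(gsub('"', "", lines[1]))
  if (first %in% COLUMN_ALIASES$cdr3b && length(lines) > 1) lines <- lines[-1]
  lines <- gsub('"', "", lines)
  background_repertoire(lines)
}

#' Construct a background repertoire
#'
#' @param tcrs Character vector of CDR3beta sequences.
#' @return A `background_repertoire`.
#' @export
background_repertoire <- function(tcrs) {
  tcrs <- validate_sequence(tcrs, "cdr3")
  structure(tcrs, class = "background_repertoire", size = length(tcrs))
}

#' @export
print.background_repertoire <- function(x, ...) {
  cat(sprintf("<background_repertoire> %d TCRs\n", attr(x, "size")))
  invisible(x)
}
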