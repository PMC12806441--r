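#' Encoding scheme for sequence pairs
#'
#' Fixes the residue-to-index mapping (alphabetical `ACDEFGHIKLMNPQRSTVWY`,
#' pad index 0) and the maximum lengths admitted per role. Sequences are
#' post-padded; true lengths are carried alongside so the recurrent scorer can
#' ignore pad positions exactly. The scheme is serialized inside every
#' checkpoint so prediction never depends on ambient configuration.
#'
#' @param max_len_cdr3,max_len_peptide Maximum admitted lengths (defaults 30).
#' @return An `encoding_scheme`.
#' @export
encoding_scheme <- function(max_len_cdr3 = 30L, max_len_peptide = 30L) {
  max_len_cdr3 <- as.integer(max_len_cdr3)
  max_len_peptide <- as.integer(max_len_peptide)
  stopifnot(max_len_cdr3 >= 1L, max_len_peptide >= 1L)
  structure(list(alphabet = AA_ALPHABET,
                 max_len_cdr3 = max_len_cdr3,
                 max_len_peptide = max_len_peptide,
                 pad_policy = "post"),
            class = "encoding_scheme")
}

#' @export
print.encoding_scheme <- function(x, ...) {
  cat(sprintf("<encoding_scheme> alphabet %s..., pad 0 (post), max CDR3 %d, max peptide %d\n",
              paste(x$alphabet[1:5], collapse = ""), x$max_len_cdr3, x$max_len_peptide))
  invisible(x)
}

# sequence -> integer index vector of length max_len (pad 0)
seq_to_indices <- function(s, max_len) {
  n <- nchar(s)
  if (n > max_len)
    stop(sprintf("sequence '%s' has length %d, exceeding the scheme maximum %d",
                 s, n, max_len), call. = FALSE)
  idx <- integer(max_len)
  idx[seq_len(n)] <- match(strsplit(s, "")[[1]], AA_ALPHABET)
  idx
}

indices_to_onehot <- function(idx) {
  m <- matrix(0L, length(idx), 20L, dimnames = list(NULL, AA_ALPHABET))
  live <- which(idx > 0L)
  m[cbind(live, idx[live])] <- 1L
  m
}

#' Encode a CDR3beta/peptide pair
#'
#' Produces both representations consumed by the scorer families: integer
#' index vectors (pad 0, residues 1..20) for the recurrent family, and the
#' equivalent one-hot matrices for the convolutional family, with true lengths
#' recorded. Deterministic; over-length sequences are an error, never
#' truncated.
#'
#' @param pair A one-row `binding_dataset` or a list with `cdr3b` and
#'   `peptide` character scalars.
#' @param scheme An [encoding_scheme].
#' @return An `encoded_pair`: list with `cdr3_indices`, `peptide_indices`,
#'   `cdr3_onehot`, `peptide_onehot`, `true_lengths`.
#' @export
encode_pair <- function(pair, scheme = encoding_scheme()) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  cdr3 <- validate_sequence(pair$cdr3b[1], "cdr3",
                            bounds = c(1L, scheme$max_len_cdr3))
  pep <- validate_sequence(pair$peptide[1], "peptide",
                           bounds = c(1L, scheme$max_len_peptide))
  ci <- seq_to_indices(cdr3, scheme$max_len_cdr3)
  pi_ <- seq_to_indices(pep, scheme$max_len_peptide)
  structure(list(cdr3_indices = ci,
                 peptide_indices = pi_,
                 cdr3_onehot = indices_to_onehot(ci),
                 peptide_onehot = indices_to_onehot(pi_),
                 true_lengths = c(cdr3 = nchar(cdr3), peptide = nchar(pep))),
            class = "encoded_pair")
}

#' Decode an index vector back to a sequence
#'
#' Exact inverse of the index encoding: `decode_indices(encode(s)) == s`.
#' Pads (index 0) are admitted only as a suffix.
#'
#' @param indices Integer vector with values in 0..20.
#' @param scheme An [encoding_scheme] (fixes the alphabet).
#' @return The decoded amino-acid sequence (character scalar).
#' @export
decode_indices <- function(indices, scheme = encoding_scheme()) {
  stopifnot(inherits(scheme, "encoding_scheme"))
  indices <- as.integer(indices)
  if (any(indices < 0L | indices > 20L))
    stop("index out of range 0..20: ", indices[which(indices < 0 | indices > 20)[1]],
         call. = FALSE)
  n <- which(indices == 0L)
  if (length(n)) {
    if (any(indices[seq(min(n), length(indices))] != 0L))
      stop("pad before residue: pad index 0 may only appear as a suffix", call. = FALSE)
    indices <- indices[indices > 0L]
  }
  if (!length(indices)) stop("all-pad index vector decodes to an empty sequence", call. = FALSE)
  paste(scheme$alphabet[indices], collapse = "")
}

# dataset -> index matrices + true lengths, as consumed by the C++ core
encode_dataset <- function(dataset, scheme) {
  n <- nrow(dataset)
  Xc <- matrix(0L, n, scheme$max_len_cdr3)
  Xp <- matrix(0L, n, scheme$max_len_peptide)
  lc <- nchar(dataset$cdr3b)
  lp <- nchar(dataset$peptide)
  if (n) {
    if (max(lc) > scheme$max_len_cdr3)
      stop("CDR3 sequence exceeds scheme maximum ", scheme$max_len_cdr3, call. = FALSE)
    if (max(lp) > scheme$max_len_peptide)
      stop("peptide sequence exceeds scheme maximum ", scheme$max_len_peptide, call. = FALSE)
    for (i in seq_len(n)) {
      Xc[i, seq_len(lc[i])] <- match(strsplit(dataset$cdr3b[i], "")[[1]], AA_ALPHABET)
      Xp[i, seq_len(lp[i])] <- match(strsplit(dataset$peptide[i], "")[[1]], AA_ALPHABET)
    }
  }
  list(Xc = Xc, lc = as.integer(lc), Xp = Xp, lp = as.integer(lp))
}
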