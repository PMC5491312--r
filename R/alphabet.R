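#' The 21-state repeat-protein alphabet
#'
#' Twenty amino acids in alphabetical one-letter order followed by the gap
#' character `"-"`.  The gap is a first-class state: it is counted in
#' frequencies, proposable during sampling, and treated as an amino acid when
#' computing the identity between repeat halves.
#'
#' @return A character vector of length 21; the gap is the last symbol.
#' @export
#' @examples
#' rf_alphabet()
rf_alphabet <- function() {
  c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")
}

#' Encode aligned sequences as integer state matrices
#'
#' @param seqs character vector of equal-length sequences.
#' @param alphabet symbol set; defaults to [rf_alphabet()].
#' @return An integer matrix (rows = sequences, columns = positions) with
#'   states in `1..length(alphabet)`.
#' @export
encode_sequences <- function(seqs, alphabet = rf_alphabet()) {
  rf_check(length(seqs) >= 1, "no sequences to encode")
  w <- unique(nchar(seqs))
  rf_check(length(w) == 1, "sequences have unequal lengths: %s",
           paste(w, collapse = ", "))
  chars <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
                  nrow = length(seqs), byrow = TRUE)
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    bad <- unique(chars[is.na(idx)])
    rf_abort("symbols outside the alphabet: %s", paste(bad, collapse = " "))
  }
  matrix(idx, nrow = length(seqs))
}

#' Decode integer state matrices back to sequences
#'
#' @param mat integer matrix of states in `1..length(alphabet)`.
#' @inheritParams encode_sequences
#' @return Character vector of sequences.
#' @export
decode_sequences <- function(mat, alphabet = rf_alphabet()) {
  rf_check(is.matrix(mat), "expected a state matrix")
  rf_check(all(mat >= 1 & mat <= length(alphabet)), "state out of range")
  apply(mat, 1, function(r) paste(alphabet[r], collapse = ""))
}

# single-character symbol set for non-standard alphabet sizes (toy models)
default_alphabet <- function(q) {
  if (q == 21) return(rf_alphabet())
  pool <- strsplit(paste0("ABCDEFGHIJKLMNOPQRSTUVWXYZ",
                          "abcdefghijklmnopqrstuvwxyz0123456789"), "")[[1]]
  rf_check(q <= length(pool), "alphabet size %d too large", q)
  pool[seq_len(q)]
}

# (i, a) -> row/column index into the (L*q) x (L*q) coupling matrix
rf_idx <- function(i, a, q) (i - 1L) * q + a

# logical mask over the (Lq x Lq) matrix selecting entries whose row
# position strictly precedes the column position (the canonical i < j half)
rf_upper_block_mask <- function(L, q) {
  pos <- rep(seq_len(L), each = q)
  outer(pos, pos, "<")
}
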