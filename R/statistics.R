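#' Identity between the two repeat halves of a pair sequence
#'
#' Counts positions `i <= L/2` where the residue equals the one at
#' `i + L/2`.  The gap is treated as an amino acid, so two aligned gaps
#' count as a match.
#'
#' @param row a pair sequence (string) of even length.
#' @return A list with `matches` (integer in `0..L/2`) and `percent`
#'   (`matches / (L/2)`).
#' @export
#' @examples
#' count_identity("ABAB")  # matches = 2, percent = 1
count_identity <- function(row) {
  L <- nchar(row)
  rf_check(L %% 2 == 0, "sequence length %d is odd", L)
  half <- L / 2
  ch <- strsplit(row, "")[[1]]
  matches <- sum(ch[1:half] == ch[half + (1:half)])
  list(matches = as.integer(matches), percent = matches / half)
}

# match counts for every row of a 1-based state matrix (columns = positions)
matrix_match_counts <- function(S) {
  half <- ncol(S) / 2
  as.integer(rowSums(S[, 1:half, drop = FALSE] ==
                       S[, half + (1:half), drop = FALSE]))
}

#' Empirical statistics of a pair alignment
#'
#' Computes the three constraint families the model is fitted to:
#' single-site frequencies `f1(i, a)`, joint frequencies `f2(i, j, a, b)`
#' for position pairs `i < j`, and the repeat-identity distribution `pid`
#' over match counts `0..L/2`.  Counts are divided by the number of rows and
#' then mixed with the uniform distribution at weight `pseudocount`
#' (`(1 - pc) f + pc/q` for `f1`, `pc/q^2` for `f2`), which keeps the
#' `ln f1` initialization of the fit finite.
#'
#' @param aln a pair [rf_alignment()].
#' @param pseudocount uniform admixture weight, `>= 0`; default `1e-5`.
#' @return An object of class `rf_statistics`: list with `f1` (L x q
#'   matrix), `f2` (symmetric `(Lq) x (Lq)` matrix, same-position blocks
#'   zero), `pid` (length `L/2 + 1`), `n_effective`, `L`, `q`, `alphabet`,
#'   `pseudocount`.
#' @export
compute_frequencies <- function(aln, pseudocount = 1e-5) {
  rf_check(inherits(aln, "rf_alignment"), "expected an rf_alignment")
  rf_check(length(aln$seqs) > 0, "empty alignment")
  rf_check(aln$pair_flag, "statistics are defined on pair alignments")
  rf_check(pseudocount >= 0, "pseudocount must be >= 0")
  S <- encode_alignment(aln)
  q <- length(aln$alphabet)
  stats <- statistics_from_matrix(S, q, pseudocount,
                                  alphabet = aln$alphabet)
  validate_statistics(stats)
  stats
}

# core counting on a state matrix; shared by compute_frequencies and the
# per-iteration model-statistics step of the fit
statistics_from_matrix <- function(S, q, pseudocount = 0, alphabet = NULL) {
  L <- ncol(S)
  n <- nrow(S)
  cnt <- cpp_pair_frequencies(S, q)
  f1 <- cnt$f1
  f2 <- cnt$f2
  if (pseudocount > 0) {
    f1 <- (1 - pseudocount) * f1 + pseudocount / q
    mask <- rf_upper_block_mask(L, q)
    f2 <- (1 - pseudocount) * f2
    f2[mask] <- f2[mask] + pseudocount / q^2
    f2[t(mask)] <- t(f2)[t(mask)]
  }
  m <- matrix_match_counts(S)
  pid <- tabulate(m + 1L, nbins = L / 2 + 1) / n
  structure(list(f1 = f1, f2 = f2, pid = pid, n_effective = n,
                 L = L, q = q,
                 alphabet = if (is.null(alphabet)) rf_alphabet() else alphabet,
                 pseudocount = pseudocount),
            class = "rf_statistics")
}

#' Check the internal consistency of frequency statistics
#'
#' Asserts, to `tol`: each `f1` row sums to 1; each `i < j` joint block sums
#' to 1 and marginalizes onto `f1`; `pid` sums to 1; all entries are
#' non-negative.
#'
#' @param stats an `rf_statistics` object.
#' @param tol numeric tolerance; default `1e-12`.
#' @return `stats`, invisibly; raises a validation error otherwise.
#' @export
validate_statistics <- function(stats, tol = 1e-12) {
  L <- stats$L; q <- stats$q
  rf_check(all(stats$f1 >= 0) && all(stats$f2 >= 0) && all(stats$pid >= 0),
           "negative frequency entry")
  rf_check(max(abs(rowSums(stats$f1) - 1)) <= tol, "f1 rows do not sum to 1")
  rf_check(length(stats$pid) == L / 2 + 1, "pid has wrong number of bins")
  rf_check(abs(sum(stats$pid) - 1) <= tol, "pid does not sum to 1")
  rf_check(max(abs(stats$f2 - t(stats$f2))) == 0, "f2 is not symmetric")
  # block sums and marginalization, vectorized over all i < j pairs
  pos <- rep(seq_len(L), each = q)
  bs <- rowsum(t(rowsum(stats$f2, pos)), pos)  # L x L block sums
  up <- upper.tri(bs)
  rf_check(max(abs(bs[up] - 1)) <= tol, "a joint block does not sum to 1")
  marg <- rowsum(t(stats$f2), pos)             # L x (Lq): sum over b per j
  for (j in seq_len(L)) {
    cols <- rf_idx(j, seq_len(q), q)
    other <- setdiff(seq_len(L), j)
    dev <- sweep(marg[other, cols, drop = FALSE], 2, stats$f1[j, ])
    rf_check(max(abs(dev)) <= tol, "f2 does not marginalize onto f1 (j = %d)", j)
  }
  invisible(stats)
}

#' Serialize statistics to JSON
#'
#' Full-precision, text-only container: `f1` dense, the canonical `i < j`
#' half of `f2` as a flat vector in column-major mask order, plus `pid` and
#' metadata.
#'
#' @param stats an `rf_statistics` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_statistics <- function(stats, path) {
  mask <- rf_upper_block_mask(stats$L, stats$q)
  obj <- list(format = "repeatfield-statistics", version = 1L,
              alphabet = paste(stats$alphabet, collapse = ""),
              L = stats$L, q = stats$q, n_effective = stats$n_effective,
              pseudocount = stats$pseudocount, pid = stats$pid,
              f1 = stats$f1, f2_upper = stats$f2[mask])
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read statistics written by [write_statistics()]
#'
#' @param path input JSON file.
#' @return An `rf_statistics` object.
#' @export
read_statistics <- function(path) {
  rf_check(file.exists(path), "statistics file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rf_check(identical(obj$format, "repeatfield-statistics"),
           "%s is not a repeatfield statistics file", path)
  L <- obj$L; q <- obj$q
  mask <- rf_upper_block_mask(L, q)
  f2 <- matrix(0, L * q, L * q)
  f2[mask] <- obj$f2_upper
  f2[t(mask)] <- t(f2)[t(mask)]
  stats <- structure(list(f1 = matrix(obj$f1, nrow = L), f2 = f2,
                          pid = obj$pid, n_effective = obj$n_effective,
                          L = L, q = q,
                          alphabet = strsplit(obj$alphabet, "")[[1]],
                          pseudocount = obj$pseudocount),
                     class = "rf_statistics")
  validate_statistics(stats, tol = 1e-9)
  stats
}
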