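#' Build a pair alignment from consecutive single repeats
#'
#' Joins repeats that are consecutive within their parent protein: for every
#' protein and every ordinal `k` such that repeats `k` and `k + 1` both
#' exist, one output row is the concatenation of the two repeat sequences.
#' Output rows are sorted by protein identifier and then by `k`.
#'
#' @param aln an [rf_alignment()] of single repeats with `protein_id` and
#'   `repeat_index` metadata.
#' @return An [rf_alignment()] with `pair_flag = TRUE` and width `2 * L`.
#' @export
build_pairs <- function(aln) {
  rf_check(inherits(aln, "rf_alignment"), "expected an rf_alignment")
  rf_check(!aln$pair_flag, "alignment is already a pair alignment")
  m <- aln$meta
  if (anyNA(m$protein_id) || anyNA(m$repeat_index)) {
    rf_abort("build_pairs requires protein_id and repeat_index metadata %s",
             "(headers of the form 'proteinID/start-end')")
  }
  ord <- order(m$protein_id, m$repeat_index)
  m <- m[ord, , drop = FALSE]
  seqs <- aln$seqs[ord]
  adj <- which(m$protein_id[-1] == m$protein_id[-nrow(m)] &
                 m$repeat_index[-1] == m$repeat_index[-nrow(m)] + 1L)
  if (length(adj) == 0) {
    rf_abort("no consecutive repeat pairs found")
  }
  pair_seqs <- paste0(seqs[adj], seqs[adj + 1L])
  meta <- data.frame(
    id = sprintf("%s/%s-%s", m$protein_id[adj],
                 ifelse(is.na(m$start[adj]), m$repeat_index[adj], m$start[adj]),
                 ifelse(is.na(m$end[adj + 1L]), m$repeat_index[adj + 1L],
                        m$end[adj + 1L])),
    protein_id = m$protein_id[adj],
    repeat_index = m$repeat_index[adj],
    start = m$start[adj],
    end = m$end[adj + 1L],
    stringsAsFactors = FALSE)
  rf_alignment(pair_seqs, meta, pair_flag = TRUE, alphabet = aln$alphabet)
}

#' Remove columns dominated by gaps
#'
#' Drops alignment columns whose gap fraction strictly exceeds
#' `max_gap_fraction` (default 0.8, i.e. "gaps in more than 80% of the
#' sequences").  For pair alignments a column `i <= L/2` and its partner
#' `i + L/2` are removed jointly, and only when both exceed the threshold,
#' so that the positional correspondence between the two repeat halves is
#' preserved.
#'
#' @param aln an [rf_alignment()].
#' @param max_gap_fraction columns with gap fraction strictly greater than
#'   this are removed; in (0, 1].
#' @return A list with `alignment` (the filtered [rf_alignment()]) and
#'   `kept` (integer indices of retained columns in the input).
#' @export
remove_gappy_columns <- function(aln, max_gap_fraction = 0.8) {
  rf_check(inherits(aln, "rf_alignment"), "expected an rf_alignment")
  rf_check(max_gap_fraction > 0 && max_gap_fraction <= 1,
           "max_gap_fraction must be in (0, 1]")
  gap_state <- length(aln$alphabet)
  S <- encode_alignment(aln)
  gap_frac <- colMeans(S == gap_state)
  gappy <- gap_frac > max_gap_fraction
  if (aln$pair_flag) {
    half <- aln$L / 2
    drop_half <- gappy[1:half] & gappy[half + (1:half)]
    drop <- c(drop_half, drop_half)
  } else {
    drop <- gappy
  }
  kept <- which(!drop)
  rf_check(length(kept) > 0, "all columns removed at gap threshold %g",
           max_gap_fraction)
  seqs <- apply(S[, kept, drop = FALSE], 1,
                function(r) paste(aln$alphabet[r], collapse = ""))
  out <- rf_alignment(seqs, aln$meta, pair_flag = aln$pair_flag,
                      alphabet = aln$alphabet)
  list(alignment = out, kept = kept)
}

#' Greedy identity clustering and representative selection
#'
#' CD-HIT-style redundancy reduction on an already-aligned set of rows:
#' sequences are sorted (most non-gap residues first, ties lexicographic),
#' each sequence joins the first existing cluster whose representative
#' matches it at `>= identity_threshold` column identity (gap treated as a
#' character), otherwise it seeds a new cluster.  No realignment is
#' performed.  The result is deterministic given the input.
#'
#' @param aln an [rf_alignment()].
#' @param identity_threshold fraction of identical columns required to join
#'   a cluster; in (0, 1].  Default 0.9 (clustering at 90% identity).
#' @param seed unused (kept for interface stability; the greedy pass is
#'   deterministic).
#' @return An [rf_alignment()] of one representative per cluster, in cluster
#'   creation order.
#' @export
cluster_representatives <- function(aln, identity_threshold = 0.9,
                                    seed = NULL) {
  rf_check(inherits(aln, "rf_alignment"), "expected an rf_alignment")
  rf_check(identity_threshold > 0 && identity_threshold <= 1,
           "identity_threshold must be in (0, 1]")
  S <- encode_alignment(aln)
  gap_state <- length(aln$alphabet)
  ord <- order(-rowSums(S != gap_state), aln$seqs)
  reps <- integer(0)  # row indices (into aln) of cluster representatives
  L <- aln$L
  for (r in ord) {
    hit <- FALSE
    for (rep_i in reps) {
      if (sum(S[r, ] == S[rep_i, ]) / L >= identity_threshold) {
        hit <- TRUE
        break
      }
    }
    if (!hit) reps <- c(reps, r)
  }
  aln_subset(aln, reps)
}
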