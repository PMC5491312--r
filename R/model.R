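#' Construct an evolutionary-field parameter set
#'
#' Houses the local fields `h`, the pairwise couplings `J` and the
#' repeat-identity potential `lambda`.  Couplings are stored as a dense
#' symmetric `(Lq) x (Lq)` matrix indexed by `(position, state)`; the
#' same-position blocks (including the diagonal) are identically zero, so
#' the energy sum effectively runs over position pairs `i < j` only.
#'
#' @param h `L x q` matrix of local fields.
#' @param J symmetric `(Lq) x (Lq)` coupling matrix with zero same-position
#'   blocks, or `NULL` for all-zero couplings.
#' @param lam identity potential, one value per match-count bin `0..L/2`,
#'   or `NULL` for zeros.
#' @param alphabet symbol set; its length must equal `ncol(h)`.
#' @return An object of class `rf_params` with elements `h`, `J`, `lam`,
#'   `L`, `q`, `alphabet`.
#' @export
rf_params <- function(h, J = NULL, lam = NULL, alphabet = rf_alphabet()) {
  rf_check(is.matrix(h) && all(is.finite(h)), "h must be a finite matrix")
  L <- nrow(h); q <- ncol(h)
  rf_check(q == length(alphabet), "ncol(h) != alphabet size")
  if (is.null(J)) J <- matrix(0, L * q, L * q)
  if (is.null(lam)) lam <- numeric(L / 2 + 1)
  rf_check(is.matrix(J) && nrow(J) == L * q && ncol(J) == L * q,
           "J must be (L*q) x (L*q)")
  rf_check(all(is.finite(J)) && all(is.finite(lam)),
           "parameters must be finite")
  rf_check(max(abs(J - t(J))) == 0, "J must be symmetric")
  same <- !rf_upper_block_mask(L, q) & !t(rf_upper_block_mask(L, q))
  rf_check(all(J[same] == 0), "same-position coupling blocks must be zero")
  rf_check(L %% 2 != 0 || length(lam) == L / 2 + 1,
           "lam must have L/2 + 1 entries")
  structure(list(h = h, J = J, lam = lam, L = L, q = q, alphabet = alphabet),
            class = "rf_params")
}

#' All-zero parameters
#' @param L alignment width.
#' @param q alphabet size (21).
#' @export
zero_params <- function(L, q = 21) {
  rf_params(matrix(0, L, q), alphabet = default_alphabet(q))
}

#' @export
print.rf_params <- function(x, ...) {
  nnz <- sum(x$J[rf_upper_block_mask(x$L, x$q)] != 0)
  cat(sprintf(
    "rf_params: L = %d, q = %d | %d fields, %d nonzero couplings, %d lambda\n",
    x$L, x$q, x$L * x$q, nnz, length(x$lam)))
  invisible(x)
}

#' Extract or replace a coupling block
#'
#' `coupling(params, i, j)` returns the `q x q` block `J_ij(a, b)`;
#' assignment sets the block and its symmetric image.
#'
#' @param params an [rf_params()].
#' @param i,j distinct positions in `1..L`.
#' @param value a `q x q` matrix (for assignment).
#' @return The `q x q` coupling block.
#' @export
coupling <- function(params, i, j) {
  rf_check(i != j, "same-position couplings are fixed to zero")
  params$J[rf_idx(i, seq_len(params$q), params$q),
           rf_idx(j, seq_len(params$q), params$q)]
}

#' @rdname coupling
#' @export
`coupling<-` <- function(params, i, j, value) {
  rf_check(i != j, "same-position couplings are fixed to zero")
  ri <- rf_idx(i, seq_len(params$q), params$q)
  rj <- rf_idx(j, seq_len(params$q), params$q)
  params$J[ri, rj] <- value
  params$J[rj, ri] <- t(value)
  params
}

#' Evolutionary energy of a pair sequence
#'
#' Evaluates `E(s) = -sum_i h_i(a_i) + sum_{i<j} J_ij(a_i, b_j) -
#' lambda(matches(s))`.  Lower is more favorable.  With
#' `use_lambda = FALSE` the identity term is dropped and the score is the
#' plain Potts energy.
#'
#' @param seq a sequence string of width `L` over the model alphabet (or a
#'   character vector of several such strings).
#' @param params an [rf_params()].
#' @param use_lambda include the repeat-identity potential (default `TRUE`).
#' @return Numeric energy, one value per input sequence.
#' @export
energy <- function(seq, params, use_lambda = TRUE) {
  S <- encode_sequences(seq, params$alphabet)
  rf_check(ncol(S) == params$L, "sequence width %d != model width %d",
           ncol(S), params$L)
  if (use_lambda) rf_check(params$L %% 2 == 0, "identity term needs even L")
  as.numeric(cpp_energies(S, params$h, params$J, params$lam, use_lambda))
}

#' Per-sequence energy table for an alignment
#'
#' @param aln a pair [rf_alignment()].
#' @inheritParams energy
#' @return data.frame with columns `id`, `energy`, `match_count`, `pct_id`.
#' @export
score_sequences <- function(aln, params, use_lambda = TRUE) {
  S <- encode_alignment(aln)
  rf_check(ncol(S) == params$L, "alignment width %d != model width %d",
           ncol(S), params$L)
  e <- as.numeric(cpp_energies(S, params$h, params$J, params$lam, use_lambda))
  m <- if (aln$L %% 2 == 0) matrix_match_counts(S) else rep(NA_integer_, nrow(S))
  data.frame(id = aln$meta$id, energy = e, match_count = m,
             pct_id = m / (aln$L / 2), stringsAsFactors = FALSE)
}

#' Parse a mutation specification string
#'
#' @param spec mutations as `"A12G"` or `"A12G;S30P"`: reference residue,
#'   1-based position, new residue.
#' @return data.frame with columns `pos`, `from`, `to`.
#' @export
parse_mutations <- function(spec) {
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([A-Z-])([0-9]+)([A-Z-])$", parts))
  bad <- which(lengths(m) != 4)
  rf_check(length(bad) == 0, "malformed mutation '%s'", parts[bad[1]])
  data.frame(pos = as.integer(vapply(m, `[`, "", 3)),
             from = vapply(m, `[`, "", 2),
             to = vapply(m, `[`, "", 4), stringsAsFactors = FALSE)
}

# validate a mutation set against a reference state vector (1-based states)
check_mutations <- function(muts, s, alphabet) {
  rf_check(nrow(muts) >= 0 && all(c("pos", "to") %in% names(muts)),
           "mutations need columns pos and to")
  if (nrow(muts) == 0) return(invisible(muts))
  rf_check(!anyDuplicated(muts$pos), "mutated positions must be distinct")
  rf_check(all(muts$pos >= 1 & muts$pos <= length(s)),
           "mutation outside the sequence (length %d)", length(s))
  to <- match(muts$to, alphabet)
  rf_check(!anyNA(to), "mutant state outside the alphabet")
  if (!is.null(muts$from)) {
    from <- match(muts$from, alphabet)
    rf_check(all(from == s[muts$pos]),
             "reference residue mismatch at position %s",
             paste(muts$pos[from != s[muts$pos]], collapse = ", "))
  }
  rf_check(all(to != s[muts$pos]),
           "mutation to the identical residue at position %s",
           paste(muts$pos[to == s[muts$pos]], collapse = ", "))
  invisible(muts)
}

#' Energy change of a set of point mutations
#'
#' Computed incrementally: only the field, coupling and identity terms that
#' touch a mutated position are re-evaluated, which matches a full
#' re-evaluation to numerical precision at a fraction of the cost.
#'
#' @param seq wildtype pair sequence of width `L`.
#' @param muts data.frame with columns `pos`, `to` (optionally `from`), as
#'   produced by [parse_mutations()].
#' @inheritParams energy
#' @return `energy(mutant) - energy(wildtype)` as a single number.
#' @export
delta_energy <- function(seq, muts, params, use_lambda = TRUE) {
  s <- as.integer(encode_sequences(seq, params$alphabet)[1, ])
  rf_check(length(s) == params$L, "sequence width %d != model width %d",
           length(s), params$L)
  check_mutations(muts, s, params$alphabet)
  if (nrow(muts) == 0) return(0)
  q <- params$q
  s2 <- s
  s2[muts$pos] <- match(muts$to, params$alphabet)
  dE <- -(sum(params$h[cbind(muts$pos, s2[muts$pos])]) -
            sum(params$h[cbind(muts$pos, s[muts$pos])]))
  # every position pair (i < j) touching a mutated position, counted once;
  # encoded as i + L*j with i < j <= L, so i is in 1..L-1 and decodes cleanly
  touched <- unique(unlist(lapply(muts$pos, function(p) {
    js <- setdiff(seq_along(s), p)
    pmin(p, js) + params$L * pmax(p, js)
  })))
  j <- touched %/% params$L
  i <- touched - params$L * j
  dE <- dE + sum(params$J[cbind(rf_idx(i, s2[i], q), rf_idx(j, s2[j], q))]) -
    sum(params$J[cbind(rf_idx(i, s[i], q), rf_idx(j, s[j], q))])
  if (use_lambda) {
    half <- params$L / 2
    m1 <- sum(s[1:half] == s[half + (1:half)])
    m2 <- sum(s2[1:half] == s2[half + (1:half)])
    dE <- dE - (params$lam[m2 + 1] - params$lam[m1 + 1])
  }
  dE
}

#' Energy decomposition of a repeat array
#'
#' Extends the pair model to an array of repeats in which only adjacent
#' repeats interact.  Each repeat `r` carries an internal energy
#' `-sum_i h_i + sum_{i<j} J_ij` evaluated with the intra-repeat (first
#' half) parameter block; each adjacent pair `(r, r+1)` carries an interface
#' energy `sum J_inter - lambda(matches(r, r+1))`.  For a two-repeat array
#' the total equals `energy()` of the concatenated sequence.
#'
#' @param repeats character vector of repeat sequences, each of width `L/2`.
#' @inheritParams energy
#' @return An object of class `rf_decomposition`: list with `internal`
#'   (per repeat), `interface` (per adjacent pair; length 0 for a single
#'   repeat) and `total`.
#' @export
decompose_array <- function(repeats, params, use_lambda = TRUE) {
  half <- params$L / 2
  rf_check(length(repeats) >= 1, "need at least one repeat")
  q <- params$q
  S <- encode_sequences(repeats, params$alphabet)
  rf_check(ncol(S) == half, "repeat width %d != L/2 = %d", ncol(S), half)
  intra <- if (half >= 2) t(utils::combn(half, 2)) else
    matrix(integer(0), 0, 2)
  internal <- vapply(seq_len(nrow(S)), function(r) {
    s <- S[r, ]
    e <- -sum(params$h[cbind(1:half, s)])
    if (nrow(intra) > 0) {
      e <- e + sum(params$J[cbind(rf_idx(intra[, 1], s[intra[, 1]], q),
                                  rf_idx(intra[, 2], s[intra[, 2]], q))])
    }
    e
  }, 0)
  inter_grid <- expand.grid(i = 1:half, j = half + (1:half))
  interface <- if (nrow(S) >= 2) {
    vapply(seq_len(nrow(S) - 1), function(r) {
      s1 <- S[r, ]
      s2 <- S[r + 1, ]
      e <- sum(params$J[cbind(rf_idx(inter_grid$i, s1[inter_grid$i], q),
                              rf_idx(inter_grid$j, s2[inter_grid$j - half], q))])
      if (use_lambda) e <- e - params$lam[sum(s1 == s2) + 1]
      e
    }, 0)
  } else {
    numeric(0)
  }
  structure(list(internal = internal, interface = interface,
                 total = sum(internal) + sum(interface)),
            class = "rf_decomposition")
}

#' Parameter counts of the pair model
#'
#' For alignment width `L` and alphabet size `q`: `L*q` local fields,
#' `((L*q)^2 - L*q)/2` couplings, and `L/2 + 1` identity potentials.  At
#' the ankyrin pair dimensions (L = 66, q = 21) this gives 1386, 959805
#' and 34.
#'
#' @param L alignment width (even).
#' @param q alphabet size, `>= 2`.
#' @return Named numeric vector `c(n_h, n_J, n_lambda)`.
#' @export
parameter_counts <- function(L, q = 21) {
  rf_check(L %% 2 == 0, "L = %d is odd; the pair model needs two equal halves", L)
  rf_check(q >= 2, "q must be >= 2")
  n <- L * q
  c(n_h = n, n_J = (n^2 - n) / 2, n_lambda = L / 2 + 1)
}

#' Write model parameters to JSON
#'
#' Single-file container: metadata and dense `h`/`lam` plus the nonzero
#' couplings as sparse `(i, j, a, b, value)` tuples over `i < j` (the L1
#' penalty typically leaves most couplings at exactly zero).  Numbers are
#' written at full precision, so a read-back is bit-exact.
#'
#' @param params an [rf_params()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  mask <- rf_upper_block_mask(params$L, params$q)
  nz <- which(params$J != 0 & mask, arr.ind = TRUE)
  q <- params$q
  obj <- list(format = "repeatfield-params", version = 1L,
              alphabet = paste(params$alphabet, collapse = ""),
              L = params$L, q = q,
              h = params$h, lam = params$lam,
              J_sparse = data.frame(
                i = (nz[, 1] - 1L) %/% q + 1L, a = (nz[, 1] - 1L) %% q + 1L,
                j = (nz[, 2] - 1L) %/% q + 1L, b = (nz[, 2] - 1L) %% q + 1L,
                value = params$J[nz]))
  # I(17) = 17 *significant* digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read model parameters written by [write_params()]
#'
#' @param path input JSON file.
#' @return An [rf_params()].
#' @export
read_params <- function(path) {
  rf_check(file.exists(path), "parameter file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rf_check(identical(obj$format, "repeatfield-params"),
           "%s is not a repeatfield parameter file", path)
  L <- obj$L; q <- obj$q
  J <- matrix(0, L * q, L * q)
  sp <- obj$J_sparse
  if (!is.null(sp) && NROW(sp) > 0) {
    ri <- rf_idx(sp$i, sp$a, q)
    rj <- rf_idx(sp$j, sp$b, q)
    J[cbind(ri, rj)] <- sp$value
    J[cbind(rj, ri)] <- sp$value
  }
  rf_params(matrix(obj$h, nrow = L), J, obj$lam,
            alphabet = strsplit(obj$alphabet, "")[[1]])
}
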