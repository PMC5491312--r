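# Independent reference implementations and fixture builders.  The oracles
# deliberately use literal loops and direct index arithmetic so they share no
# code path with the vectorized / compiled implementations they check.

# literal three-loop energy evaluator over E = -sum h + sum_{i<j} J - lambda
oracle_energy <- function(seq, params, use_lambda = TRUE) {
  ch <- strsplit(seq, "")[[1]]
  s <- match(ch, params$alphabet)
  L <- params$L
  q <- params$q
  e <- 0
  for (i in seq_len(L)) e <- e - params$h[i, s[i]]
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (j > i) {
        e <- e + params$J[(i - 1) * q + s[i], (j - 1) * q + s[j]]
      }
    }
  }
  if (use_lambda) {
    m <- 0
    half <- L / 2
    for (i in seq_len(half)) if (ch[i] == ch[i + half]) m <- m + 1
    e <- e - params$lam[m + 1]
  }
  e
}

# scalar reference of the four-branch L1 proximal coupling update
oracle_l1_scalar <- function(J, gap, eps, gamma) {
  if (J == 0 && abs(gap) <= gamma) return(0)
  if (J == 0) return(-eps * (gap - gamma * sign(gap)))
  cand <- J - eps * gap - eps * gamma * sign(J)
  if (cand * J > 0) cand else 0
}

# exact Boltzmann distribution by full enumeration of all q^L sequences
oracle_boltzmann <- function(params, use_lambda = TRUE) {
  grid <- expand.grid(rep(list(seq_len(params$q)), params$L))
  seqs <- apply(as.matrix(grid), 1, function(r)
    paste(params$alphabet[r], collapse = ""))
  e <- vapply(seqs, oracle_energy, 0, params = params,
              use_lambda = use_lambda, USE.NAMES = FALSE)
  w <- exp(-e)
  setNames(w / sum(w), seqs)
}

# greedy all-vs-all clustering reference (same semantics as
# cluster_representatives, written independently with explicit loops)
oracle_cluster_reps <- function(seqs, threshold, gap = "-") {
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  nongap <- vapply(chars, function(c) sum(c != gap), 0L)
  ord <- order(-nongap, unlist(seqs))
  rep_rows <- c()
  for (r in ord) {
    placed <- FALSE
    for (p in rep_rows) {
      ident <- sum(chars[[r]] == chars[[p]]) / length(chars[[r]])
      if (ident >= threshold) {
        placed <- TRUE
        break
      }
    }
    if (!placed) rep_rows <- c(rep_rows, r)
  }
  sort(rep_rows)
}

tv_distance <- function(p, q) sum(abs(p - q)) / 2

# random dense-ish parameters for oracle comparisons
make_test_params <- function(L, q, seed, density = 0.5, lam_scale = 1) {
  spec <- generator_spec(L = L, q = q, n_sequences = 1, seed = seed,
                         coupling_density = density,
                         lambda_profile = "none")
  p <- make_model(spec)
  set.seed(seed + 1000)
  p$lam <- rnorm(L / 2 + 1, 0, lam_scale)
  p
}

random_seq <- function(L, alphabet, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(alphabet, L, replace = TRUE), collapse = "")
}

# apply a state permutation consistently to parameters (gauge relabeling)
permute_params <- function(params, perm) {
  q <- params$q
  L <- params$L
  h2 <- params$h
  h2[, perm] <- params$h
  big <- rep((seq_len(L) - 1) * q, each = q) + perm
  J2 <- params$J
  J2[big, big] <- params$J
  rf_params(h2, J2, params$lam, alphabet = params$alphabet)
}

# fixture: single-repeat alignment with PFAM-style headers
write_repeat_fasta <- function(path, entries) {
  writeLines(unlist(lapply(names(entries), function(h)
    c(paste0(">", h), entries[[h]]))), path)
  path
}

# explicit (position, state) -> flat index arithmetic for tests
rf_idx_test <- function(i, a, q) (i - 1L) * q + a

# replace one character of a string
sub_at <- function(s, pos, ch) {
  substr(s, pos, pos) <- ch
  s
}

# random parameters symmetrized under repeat exchange: second-half fields and
# intra-repeat coupling blocks mirror the first half.  The repeat-array
# decomposition (which reuses the first-half intra block for every repeat)
# agrees exactly with the pair energy only in this regime.
make_symmetric_params <- function(L, q, seed, density = 0.5, lam_scale = 1) {
  p <- make_test_params(L, q, seed, density, lam_scale)
  half <- L / 2
  p$h[half + (1:half), ] <- p$h[1:half, , drop = FALSE]
  if (half >= 2) {
    for (i in 1:(half - 1)) {
      for (j in (i + 1):half) {
        coupling(p, i + half, j + half) <- coupling(p, i, j)
      }
    }
  }
  p
}
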