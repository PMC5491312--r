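#' Metropolis sampler configuration
#'
#' @param n_sequences number of sequences to record.
#' @param thin Monte Carlo steps between recorded sequences (default 1000,
#'   the value used when constructing production ensembles).
#' @param burn_in steps discarded before recording; default `10 * thin`.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @param initial `"random"` or a starting sequence string of width `L`.
#' @return An object of class `rf_sampler_config`.
#' @export
sampler_config <- function(n_sequences, thin = 1000, burn_in = 10 * thin,
                           seed = NULL, initial = "random") {
  rf_check(n_sequences >= 1, "n_sequences must be >= 1")
  rf_check(thin >= 1, "thin must be >= 1")
  rf_check(burn_in >= 0, "burn_in must be >= 0")
  structure(list(n_sequences = as.integer(n_sequences),
                 thin = as.integer(thin), burn_in = as.integer(burn_in),
                 seed = seed, initial = initial),
            class = "rf_sampler_config")
}

#' Sample a sequence ensemble from the model's Boltzmann distribution
#'
#' Single-spin-flip Metropolis Monte Carlo at temperature 1: starting from a
#' random string of `L` states (gap included), each step proposes a point
#' substitution at a uniformly chosen position to a uniformly chosen
#' different state, and accepts it when the energy drops, or else with
#' probability `exp(-dE)`.  One sequence is recorded every `thin` steps
#' after `burn_in` discarded steps.  Deterministic given `cfg$seed`.
#'
#' @param params an [rf_params()].
#' @param cfg an [sampler_config()].
#' @param use_lambda include the repeat-identity potential (default `TRUE`).
#' @return An [rf_alignment()] with `pair_flag = TRUE` for even `L`.
#' @export
metropolis_sample <- function(params, cfg, use_lambda = TRUE) {
  rf_check(inherits(cfg, "rf_sampler_config"), "expected a sampler_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  S <- sample_state_matrix(params, cfg$n_sequences, cfg$thin, cfg$burn_in,
                           cfg$initial, use_lambda)
  ids <- sprintf("mc%06d", seq_len(nrow(S)))
  rf_alignment(decode_sequences(S, params$alphabet),
               meta = data.frame(id = ids, protein_id = ids,
                                 stringsAsFactors = FALSE),
               pair_flag = params$L %% 2 == 0, alphabet = params$alphabet)
}

# raw-matrix sampling core shared with the fit loop (skips the alignment
# container and its decode cost)
sample_state_matrix <- function(params, n, thin, burn_in,
                                initial = "random", use_lambda = TRUE) {
  init <- if (identical(initial, "random")) {
    sample.int(params$q, params$L, replace = TRUE)
  } else {
    as.integer(encode_sequences(initial, params$alphabet)[1, ])
  }
  rf_check(length(init) == params$L, "initial sequence width != L")
  if (use_lambda) rf_check(params$L %% 2 == 0, "identity term needs even L")
  cpp_metropolis(params$h, params$J, params$lam, as.integer(n),
                 as.integer(thin), as.integer(burn_in), init, use_lambda)
}

#' Uniform random amino-acid sequences (negative control)
#'
#' Independent uniform draws over the 20 amino acids (the gap state is
#' excluded unless `include_gaps = TRUE`).  Used as the negative control
#' when checking that the fitted energy separates family members from
#' arbitrary polypeptides.
#'
#' @param L sequence width.
#' @param n number of sequences.
#' @param include_gaps draw over all 21 states instead of 20.
#' @param seed RNG seed, or `NULL`.
#' @return An [rf_alignment()] (`pair_flag = TRUE` when `L` is even).
#' @export
random_sequences <- function(L, n, include_gaps = FALSE, seed = NULL) {
  rf_check(n >= 1, "n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  q_eff <- if (include_gaps) 21L else 20L
  S <- matrix(sample.int(q_eff, n * L, replace = TRUE), nrow = n)
  ids <- sprintf("rand%06d", seq_len(n))
  rf_alignment(decode_sequences(S, rf_alphabet()),
               meta = data.frame(id = ids, protein_id = ids,
                                 stringsAsFactors = FALSE),
               pair_flag = L %% 2 == 0)
}
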