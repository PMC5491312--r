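#' Consensus sequence of a family
#'
#' Per column, the most frequent amino acid; the gap state is excluded from
#' the argmax (a consensus is a designable sequence of residues), and ties
#' break toward the alphabetically first residue.
#'
#' @param stats an `rf_statistics` object.
#' @return A consensus sequence string of width `L`.
#' @export
consensus_sequence <- function(stats) {
  q <- stats$q
  res <- stats$f1[, -q, drop = FALSE]  # gap is the last state
  paste(stats$alphabet[apply(res, 1, which.max)], collapse = "")
}

#' Fraction of positions identical to the consensus
#'
#' @param seq a sequence string.
#' @param consensus the consensus string, same width.
#' @return `matches / L`.
#' @export
identity_to_consensus <- function(seq, consensus) {
  rf_check(nchar(seq) == nchar(consensus),
           "sequence width %d != consensus width %d",
           nchar(seq), nchar(consensus))
  a <- strsplit(seq, "")[[1]]
  b <- strsplit(consensus, "")[[1]]
  mean(a == b)
}

#' Energy versus repeat identity (and consensus identity)
#'
#' Scores every sequence of an ensemble and tabulates its energy against
#' the identity between its two repeat halves and, when a consensus is
#' supplied, against its identity to the consensus.  On ensembles sampled
#' from a fitted model with an identity potential favoring similar repeats,
#' energy and repeat identity correlate negatively (low-energy sequences
#' have similar halves).
#'
#' @param ensemble a pair [rf_alignment()].
#' @param params an [rf_params()].
#' @param consensus optional consensus string (see [consensus_sequence()]);
#'   if omitted the consensus-identity column is `NA`.
#' @param use_lambda include the identity potential in the score.
#' @return data.frame with columns `id`, `energy`, `pct_id_between_repeats`,
#'   `pct_id_to_consensus`.
#' @export
energy_vs_identity <- function(ensemble, params, consensus = NULL,
                               use_lambda = TRUE) {
  rf_check(ensemble$pair_flag, "expected a pair alignment")
  tab <- score_sequences(ensemble, params, use_lambda = use_lambda)
  cons_id <- if (is.null(consensus)) NA_real_ else
    vapply(ensemble$seqs, identity_to_consensus, 0, consensus = consensus,
           USE.NAMES = FALSE)
  data.frame(id = tab$id, energy = tab$energy,
             pct_id_between_repeats = tab$pct_id,
             pct_id_to_consensus = cons_id, stringsAsFactors = FALSE)
}

#' Read a table of mutation experiments
#'
#' Tab-separated with columns `id`, `wt_sequence`, `mutations` (e.g.
#' `"A12G;S30P"`), `ddg`, `ddg_sd`, `convention`, `exclude`.  The
#' `convention` column declares the sign of the experimental scale:
#' `"destab_positive"` when a destabilizing mutation has positive ddG
#' (ddG = dG_wt - dG_mut) or `"destab_negative"` for the opposite
#' (ddG = dG_mut - dG_wt).  `exclude` rows (e.g. proline structural
#' disruptors) are scored but left out of the linear fit.  Lines starting
#' with `#` are comments.
#'
#' @param path input TSV file.
#' @return A list of `rf_mutation_experiment` objects.
#' @export
read_mutation_table <- function(path) {
  rf_check(file.exists(path), "mutation table not found: %s", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "wt_sequence", "mutations", "ddg", "convention")
  miss <- setdiff(need, names(tab))
  rf_check(length(miss) == 0, "mutation table lacks columns: %s",
           paste(miss, collapse = ", "))
  if (is.null(tab$ddg_sd)) tab$ddg_sd <- NA_real_
  if (is.null(tab$exclude)) tab$exclude <- FALSE
  lapply(seq_len(nrow(tab)), function(r) {
    mutation_experiment(id = tab$id[r], wt = toupper(tab$wt_sequence[r]),
                        mutations = tab$mutations[r], ddg = tab$ddg[r],
                        ddg_sd = tab$ddg_sd[r],
                        convention = tab$convention[r],
                        exclude = as.logical(tab$exclude[r]))
  })
}

#' Construct a mutation experiment
#'
#' @param id experiment label.
#' @param wt wildtype repeat-array sequence (width a multiple of one repeat).
#' @param mutations mutation string, see [parse_mutations()].
#' @param ddg experimental ddG (kcal/mol).
#' @param ddg_sd its standard deviation.
#' @param convention `"destab_positive"` or `"destab_negative"` (see
#'   [read_mutation_table()]).
#' @param exclude leave this row out of the linear fit.
#' @return An object of class `rf_mutation_experiment`.
#' @export
mutation_experiment <- function(id, wt, mutations, ddg, ddg_sd = NA,
                                convention = "destab_positive",
                                exclude = FALSE) {
  rf_check(is.finite(ddg), "ddg must be finite (experiment '%s')", id)
  rf_check(convention %in% c("destab_positive", "destab_negative"),
           "unknown ddG sign convention '%s'", convention)
  structure(list(id = id, wt = wt, muts = parse_mutations(mutations),
                 ddg = ddg, ddg_sd = ddg_sd, convention = convention,
                 exclude = isTRUE(exclude)),
            class = "rf_mutation_experiment")
}

# model energy change of an experiment's mutations on its repeat array
experiment_delta_energy <- function(exp, params, use_lambda = TRUE) {
  half <- params$L / 2
  wlen <- nchar(exp$wt)
  rf_check(wlen %% half == 0,
           "wildtype of '%s' (width %d) is not an array of width-%d repeats",
           exp$id, wlen, half)
  reps <- substring(exp$wt, seq(1, wlen, half), seq(half, wlen, half))
  s <- as.integer(encode_sequences(exp$wt, params$alphabet)[1, ])
  check_mutations(exp$muts, s, params$alphabet)
  mt <- strsplit(exp$wt, "")[[1]]
  mt[exp$muts$pos] <- exp$muts$to
  mut <- paste(mt, collapse = "")
  reps_mut <- substring(mut, seq(1, wlen, half), seq(half, wlen, half))
  decompose_array(reps_mut, params, use_lambda)$total -
    decompose_array(reps, params, use_lambda)$total
}

#' Mutation ddG prediction from the evolutionary field
#'
#' Computes the model energy change of every experiment (via the repeat
#' array decomposition, so wildtypes longer than one pair are handled),
#' aligns experimental signs onto the canonical destabilizing-positive
#' scale declared per experiment, and fits the least-squares line of the
#' energy change on the experimental ddG over the non-excluded rows.  Sign
#' agreement (destabilizing predicted as energy increase) is reported over
#' all experiments.
#'
#' @param experiments list of [mutation_experiment()] objects.
#' @param params an [rf_params()].
#' @param use_lambda include the identity potential.
#' @return A list of class `rf_ddg_fit`: `table` (data.frame with `id`,
#'   `delta_energy`, `ddg`, `ddg_destab`, `excluded`), `slope`,
#'   `intercept`, `r_squared` (NA when fewer than two usable points),
#'   `sign_agreement`, `n_fit`, `n_excluded`.
#' @export
predict_ddG <- function(experiments, params, use_lambda = TRUE) {
  rf_check(length(experiments) >= 1, "no experiments")
  if (inherits(experiments, "rf_mutation_experiment")) {
    experiments <- list(experiments)
  }
  de <- vapply(experiments, experiment_delta_energy, 0, params = params,
               use_lambda = use_lambda)
  ddg <- vapply(experiments, `[[`, 0, "ddg")
  conv <- vapply(experiments, `[[`, "", "convention")
  excl <- vapply(experiments, `[[`, TRUE, "exclude")
  ddg_destab <- ifelse(conv == "destab_negative", -ddg, ddg)
  tab <- data.frame(id = vapply(experiments, `[[`, "", "id"),
                    delta_energy = de, ddg = ddg, ddg_destab = ddg_destab,
                    excluded = excl, stringsAsFactors = FALSE)
  use <- !excl
  n_fit <- sum(use)
  if (n_fit >= 2 && var(ddg_destab[use]) > 0) {
    fit <- lm(de[use] ~ ddg_destab[use])
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    # summary.lm warns on a perfect fit; exact synthetic data is legitimate
    r2 <- suppressWarnings(summary(fit)$r.squared)
  } else {
    slope <- intercept <- r2 <- NA_real_
  }
  structure(list(table = tab, slope = slope, intercept = intercept,
                 r_squared = r2,
                 sign_agreement = mean(sign(de) == sign(ddg_destab)),
                 n_fit = n_fit, n_excluded = sum(excl)),
            class = "rf_ddg_fit")
}

#' Position pairs carrying the most extreme couplings
#'
#' Ranks the nonzero couplings (over position pairs `i < j`, all state
#' combinations) and reports, for the `top_k` largest and `bottom_k`
#' smallest values, the position pairs involved together with how many
#' state combinations of that pair made the selection.  When fewer nonzero
#' couplings exist than requested, all of them are returned without
#' padding.
#'
#' @param params an [rf_params()].
#' @param top_k,bottom_k how many extreme coupling values to select at each
#'   end.
#' @return data.frame with columns `i`, `j`, `n_combos`, `rank_tag`
#'   (`"top"`/`"bottom"`), ordered by extremeness of each pair's best entry.
#' @export
extreme_couplings <- function(params, top_k = 200, bottom_k = 200) {
  q <- params$q
  mask <- rf_upper_block_mask(params$L, q)
  nz <- which(params$J != 0 & mask, arr.ind = TRUE)
  if (nrow(nz) == 0) {
    return(data.frame(i = integer(0), j = integer(0),
                      n_combos = integer(0), rank_tag = character(0)))
  }
  vals <- unname(params$J[nz])
  pos_i <- unname((nz[, 1] - 1L) %/% q + 1L)
  pos_j <- unname((nz[, 2] - 1L) %/% q + 1L)
  pick <- function(ord, k, tag) {
    sel <- head(ord, max(0, min(k, length(ord))))
    key <- paste(pos_i[sel], pos_j[sel])
    first <- !duplicated(key)
    data.frame(i = pos_i[sel][first], j = pos_j[sel][first],
               n_combos = as.integer(table(key)[key[first]]),
               rank_tag = rep(tag, sum(first)), stringsAsFactors = FALSE)
  }
  out <- rbind(pick(order(vals, decreasing = TRUE), top_k, "top"),
               pick(order(vals), bottom_k, "bottom"))
  rownames(out) <- NULL
  out
}

#' Read a plain-text binary contact map
#'
#' Whitespace-delimited `L x L` matrix of 0/1 entries; must be symmetric
#' with a zero diagonal.
#'
#' @param path input file.
#' @return An integer matrix of class `rf_contact_map`.
#' @export
read_contact_map <- function(path) {
  rf_check(file.exists(path), "contact map not found: %s", path)
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  rf_check(nrow(m) == ncol(m), "contact map is not square")
  rf_check(all(m %in% c(0, 1)), "contact map entries must be 0/1")
  rf_check(all(m == t(m)), "contact map is not symmetric")
  rf_check(all(diag(m) == 0), "contact map diagonal must be zero")
  structure(m, class = c("rf_contact_map", class(m)))
}

#' Overlap of extreme couplings with native contacts
#'
#' Fraction of extreme-coupling position pairs that are either in contact
#' in the native structure or are equivalent positions of the two repeat
#' halves (`j = i + L/2`, the same residue of the adjacent repeat).
#'
#' @param extremes data.frame with columns `i`, `j` (see
#'   [extreme_couplings()]).
#' @param cmap an `L x L` 0/1 matrix (see [read_contact_map()]).
#' @param repeat_offset offset identifying equivalent positions; default
#'   `ncol(cmap) / 2`.
#' @return The overlap fraction in `[0, 1]`.
#' @export
coupling_contact_overlap <- function(extremes, cmap,
                                     repeat_offset = ncol(cmap) / 2) {
  rf_check(nrow(extremes) > 0, "no extreme couplings supplied")
  pairs <- unique(extremes[, c("i", "j")])
  rf_check(max(pairs$j) <= ncol(cmap),
           "coupling position %d exceeds contact map width %d",
           max(pairs$j), ncol(cmap))
  hit <- cmap[cbind(pairs$i, pairs$j)] == 1 |
    (pairs$j - pairs$i) == repeat_offset
  mean(hit)
}
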