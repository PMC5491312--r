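#' Fit configuration
#'
#' Learning settings for the Monte Carlo gradient descent.  Production-scale
#' fits of real families use ensembles of 80000 sequences per iteration; the
#' default here is the desk-scale 5000, which keeps a full fit on a
#' width-12 toy family within minutes on one CPU.  Learning rates are
#' engineering choices with no canonical values; the
#' identity-potential rate is much larger than the others because its
#' gradient is bounded by a probability difference across only `L/2 + 1`
#' bins while the potential itself must reach order-10 values to shape the
#' identity tail.
#'
#' @param eps_h,eps_j,eps_id learning rates for fields, couplings and the
#'   identity potential.
#' @param gamma L1 strength on couplings, in frequency units; a dormant
#'   coupling activates only when its frequency gap exceeds `gamma`.
#' @param mc_n Monte Carlo ensemble size per iteration.
#' @param mc_thin,mc_burn_in sampler thinning and burn-in per iteration.
#' @param tol convergence tolerance: iteration stops when the maximum
#'   absolute difference between empirical and model statistics (over `f1`,
#'   `f2` and `pid` jointly) falls below `tol`.  Default 0.02, the
#'   stopping rule matched to the sampling error of the data itself.
#' @param confirm_n ensemble size used to confirm the stopping rule: when
#'   the per-iteration errors dip below `tol`, a larger ensemble re-measures
#'   them before the fit is declared converged, so that the criterion
#'   gauges the model rather than the gradient noise.  Default `4 * mc_n`.
#' @param max_iters iteration cap; hitting it returns the best parameters
#'   seen with a flagged trace rather than an error.
#' @param decay geometric per-iteration decay of all learning rates.
#' @param seed base seed; iteration `k` seeds the sampler with `seed + k`.
#' @return An object of class `rf_fit_config`.
#' @export
fit_config <- function(eps_h = 0.5, eps_j = 2, eps_id = 5, gamma = 1e-3,
                       mc_n = 5000, mc_thin = 1000, mc_burn_in = 10 * mc_thin,
                       tol = 0.02, max_iters = 500, decay = 0.998, seed = 1,
                       confirm_n = 4 * mc_n) {
  rf_check(eps_h > 0 && eps_j > 0 && eps_id > 0, "learning rates must be > 0")
  rf_check(gamma >= 0, "gamma must be >= 0")
  rf_check(tol > 0, "tol must be > 0")
  rf_check(mc_n >= 1 && mc_thin >= 1 && mc_burn_in >= 0, "bad MC settings")
  rf_check(confirm_n >= mc_n, "confirm_n must be >= mc_n")
  structure(list(eps_h = eps_h, eps_j = eps_j, eps_id = eps_id, gamma = gamma,
                 mc_n = as.integer(mc_n), mc_thin = as.integer(mc_thin),
                 mc_burn_in = as.integer(mc_burn_in), tol = tol,
                 max_iters = as.integer(max_iters), decay = decay,
                 seed = as.integer(seed), confirm_n = as.integer(confirm_n)),
            class = "rf_fit_config")
}

#' Site-independent initialization
#'
#' `h = ln f1`, `J = 0`, `lambda = 0`: the site-independent model, whose
#' Boltzmann marginals reproduce `f1` exactly.  Requires pseudocounted
#' statistics so the logarithm is finite.
#'
#' @param stats an `rf_statistics` object.
#' @return An [rf_params()].
#' @export
init_parameters <- function(stats) {
  if (any(stats$f1 <= 0)) {
    rf_abort("f1 contains zero frequencies; recompute statistics with a %s",
             "positive pseudocount before initializing")
  }
  rf_params(log(stats$f1), alphabet = stats$alphabet)
}

#' One L1-regularized coupling update
#'
#' The four-branch proximal rule applied elementwise, with `gap` the
#' frequency mismatch `f2 - f2_model`:
#' \itemize{
#'   \item dormant (`J = 0`) and `|gap| <= gamma`: stays exactly 0;
#'   \item dormant and `|gap| > gamma`: activates with the thresholded
#'     gradient step `-eps * (gap - gamma * sign(gap))`;
#'   \item active: takes the step `J - eps * gap - eps * gamma * sign(J)`
#'     provided the result keeps the sign of `J`;
#'   \item active with sign crossing: clipped to exactly 0.
#' }
#' The gradient direction makes an over-represented empirical pair
#' (`gap > 0`) more favorable, i.e. pushes its coupling down (couplings
#' enter the energy with a positive sign, and low energy means high
#' probability).
#'
#' @param J current coupling matrix (any shape; applied elementwise).
#' @param gap `f2 - f2_model`, same shape.
#' @param eps learning rate.
#' @param gamma L1 strength in frequency units.
#' @return Updated couplings, same shape as `J`.
#' @export
coupling_update_l1 <- function(J, gap, eps, gamma) {
  dormant <- J == 0
  out <- J
  activate <- dormant & abs(gap) > gamma
  out[dormant] <- 0
  out[activate] <- -eps * (gap[activate] - gamma * sign(gap[activate]))
  act <- !dormant
  cand <- J[act] - eps * gap[act] - eps * gamma * sign(J[act])
  out[act] <- ifelse(cand * J[act] > 0, cand, 0)
  out
}

# maximum absolute statistic mismatches between two statistic sets
stat_errors <- function(stats, f1m, f2m, pidm) {
  c(f1 = max(abs(stats$f1 - f1m)),
    f2 = max(abs(stats$f2 - f2m)),
    pid = max(abs(stats$pid - pidm)))
}

#' Fit the evolutionary field by Monte Carlo gradient descent
#'
#' Starting from the site-independent initialization, each iteration (1)
#' samples `mc_n` sequences from the current model by Metropolis Monte
#' Carlo, (2) measures the model's `f1`, `f2` and `pid`, (3) moves the
#' fields toward under-reproduced residues
#' (`h <- h + eps_h (f1 - f1_model)`), (4) updates the couplings with the
#' L1 proximal rule of [coupling_update_l1()], and (5) updates the identity
#' potential (`lambda <- lambda + eps_id (pid - pid_model)`).  Iteration
#' stops when the maximum statistic mismatch falls below `cfg$tol` — first
#' measured on the working ensemble, then confirmed on a `cfg$confirm_n`
#' ensemble so that stopping reflects the model rather than Monte Carlo
#' noise (a confirmation sample's statistics also feed the next update if
#' the fit continues) — or at `cfg$max_iters`, in which case the best
#' parameters seen are returned and the trace is flagged
#' (`converged = FALSE`), not an error.
#'
#' @param stats empirical `rf_statistics` (see [compute_frequencies()]).
#' @param cfg an [fit_config()].
#' @return A list of class `rf_fit` with `params` (an [rf_params()]),
#'   `trace` (data.frame: `iter`, `err_f1`, `err_f2`, `err_pid`, `nnz_j`,
#'   `steps`) and `converged`.
#' @export
fit <- function(stats, cfg = fit_config()) {
  rf_check(inherits(stats, "rf_statistics"), "expected rf_statistics")
  rf_check(inherits(cfg, "rf_fit_config"), "expected rf_fit_config")
  validate_statistics(stats, tol = 1e-9)
  params <- init_parameters(stats)
  L <- stats$L; q <- stats$q
  mask <- rf_upper_block_mask(L, q)
  trace <- vector("list", cfg$max_iters)
  best <- list(err = Inf, params = params)
  converged <- FALSE
  rate <- 1
  steps_per_iter <- cfg$mc_burn_in + as.numeric(cfg$mc_n) * cfg$mc_thin
  for (k in seq_len(cfg$max_iters)) {
    set.seed(cfg$seed + k)
    S <- sample_state_matrix(params, cfg$mc_n, cfg$mc_thin, cfg$mc_burn_in)
    mstats <- statistics_from_matrix(S, q)
    err <- stat_errors(stats, mstats$f1, mstats$f2, mstats$pid)
    if (max(err) < cfg$tol && cfg$confirm_n > cfg$mc_n) {
      # the working ensemble says "converged"; confirm on a larger sample
      # so the stopping rule measures the model, not the gradient noise
      set.seed(cfg$seed + k + 500000L)
      S <- sample_state_matrix(params, cfg$confirm_n, cfg$mc_thin,
                               cfg$mc_burn_in)
      mstats <- statistics_from_matrix(S, q)
      err <- stat_errors(stats, mstats$f1, mstats$f2, mstats$pid)
    }
    nnz <- sum(params$J[mask] != 0)
    trace[[k]] <- data.frame(iter = k, err_f1 = err[["f1"]],
                             err_f2 = err[["f2"]], err_pid = err[["pid"]],
                             nnz_j = nnz, steps = k * steps_per_iter)
    if (max(err) < best$err) best <- list(err = max(err), params = params)
    if (max(err) < cfg$tol) {
      converged <- TRUE
      break
    }
    params$h <- params$h + cfg$eps_h * rate * (stats$f1 - mstats$f1)
    params$J <- coupling_update_l1(params$J, stats$f2 - mstats$f2,
                                   cfg$eps_j * rate, cfg$gamma)
    params$lam <- params$lam + cfg$eps_id * rate * (stats$pid - mstats$pid)
    rate <- rate * cfg$decay
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, TRUE)])
  if (!converged) {
    warning(sprintf("fit did not reach tol = %g in %d iterations %s",
                    cfg$tol, cfg$max_iters,
                    "(returning best parameters seen)"))
    params <- best$params
  }
  structure(list(params = params, trace = trace, converged = converged),
            class = "rf_fit")
}

#' @export
print.rf_fit <- function(x, ...) {
  last <- tail(x$trace, 1)
  cat(sprintf(
    "rf_fit: %s after %d iterations | max errors f1 %.4f f2 %.4f pid %.4f\n",
    if (x$converged) "converged" else "NOT converged", nrow(x$trace),
    last$err_f1, last$err_f2, last$err_pid))
  invisible(x)
}

#' Convergence report from a fresh model ensemble
#'
#' Draws a new Metropolis sample from `params` and returns the maximum
#' absolute mismatch against the empirical statistics, separately for the
#' single-site frequencies, the joint frequencies and the identity
#' distribution.  The fit is considered converged when all three are below
#' 0.02, the stopping rule tied to the sampling error of the data.
#'
#' @param stats empirical `rf_statistics`.
#' @param params an [rf_params()].
#' @param mc_n,mc_thin,mc_burn_in ensemble settings for the fresh sample.
#' @param seed RNG seed.
#' @return Named numeric vector `c(f1, f2, pid)` of maximum absolute errors.
#' @export
convergence_report <- function(stats, params, mc_n = 20000, mc_thin = 1000,
                               mc_burn_in = 10 * mc_thin, seed = 1) {
  rf_check(params$L == stats$L && params$q == stats$q,
           "parameter and statistic dimensions disagree")
  if (!is.null(seed)) set.seed(seed)
  S <- sample_state_matrix(params, mc_n, mc_thin, mc_burn_in)
  mstats <- statistics_from_matrix(S, stats$q)
  stat_errors(stats, mstats$f1, mstats$f2, mstats$pid)
}
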