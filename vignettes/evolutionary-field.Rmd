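---
title: "Evolutionary energy fields for repeat proteins: model, inference and design choices"
author: "repeatfield developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary energy fields for repeat proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(repeatfield)
```

## The model and its assumptions

`repeatfield` models the sequence statistics of a repeat-protein family at
the level of **pairs of consecutive repeats**: the smallest unit that
contains both the repeat-repeat interface and a measurable identity between
neighbors.  A pair sequence `s` of `L` aligned columns over `q = 21` states
(20 amino acids and the gap, which is a first-class state throughout) is
scored by

$$E(s) = -\sum_{i=1}^{L} h_i(a_i) + \sum_{i<j} J_{ij}(a_i, b_j) - \lambda_{Id}(s),$$

with the convention that lower energy means higher compatibility, and the
population of sequences assumed Boltzmann-distributed,
$P(s) \propto e^{-E(s)}$.  The three parameter families are matched to
three empirical constraint families:

| parameters | count | constraint |
|---|---|---|
| fields `h_i(a)` | `L·q` | single-site frequencies `f_i(a)` |
| couplings `J_ij(a,b)`, `i<j` | `((Lq)² − Lq)/2` | joint frequencies `f_ij(a,b)` |
| identity potential `λ(k)`, `k = 0..L/2` | `L/2 + 1` | repeat-identity distribution `p_id` |

The identity potential is the model's repeat-specific ingredient: natural
consecutive repeats show a populated high-identity tail that neither fields
nor pairwise couplings reproduce, presumably because repeat arrays also
evolve by duplication.  `λ(k)` acts on the number of positions at which the
two halves carry the same state (gap–gap counts as a match), which makes it
a single scalar potential on a derived statistic — a minimal handle on
higher-order correlation.

Self-couplings `J_ii` are fixed to zero (they are degenerate with `h_i`),
and the energy sum runs over `i < j` only; the ankyrin parameter count
`959805 = ((66·21)² − 66·21)/2` is consistent with this reading even though
it enumerates all distinct `(position, state)` pairs.

**Gauge freedom.**  Potts parameterizations are not identifiable: families
of transformations of `(h, J)` leave `P(s)` unchanged, and `λ` overlaps
with the part of `J` that links equivalent positions of the two halves.  We
fix no explicit gauge; the L1 penalty during inference simply selects a
sparse representative.  Consequently **all cross-model comparisons are made
on statistics and energies, never on raw parameter values**, and the
test-suite asserts parameter recovery only at the level of reproduced
statistics.

## Preprocessing

* Repeat pairs are built by concatenating repeats that are consecutive
  (ordinal `k`, `k+1`) within their parent protein, with repeat order taken
  from the start coordinates in PFAM-style `protein/start-end` headers.
* Columns with gaps in **strictly more than** 80% of sequences are removed
  (`remove_gappy_columns()`; the boundary case of exactly 80% is kept, a
  literal reading of "more than").  For pair alignments a column and its
  partner at offset `L/2` are removed jointly, and only when *both* exceed
  the threshold.  The joint rule is our choice, not an upstream statement:
  it preserves the positional correspondence on which the identity count
  and `λ` rest, at the price of keeping a few gappier columns.
* Redundancy reduction follows the CD-HIT recipe in spirit — greedy
  incremental clustering at 90% identity with one representative per
  cluster — but is reimplemented in-package on the *already aligned* rows
  (identity = identical columns / width, no realignment), removing the
  external binary dependency.
* Non-standard residues (B, Z, X, U, O) and any other out-of-alphabet
  character map to the gap state, with a warning that counts the
  substitutions.

## Statistics and the pseudocount

Frequencies are plain counts over rows divided by the row count, then mixed
with the uniform distribution at weight `pc` (`1e-5` by default):
`f1 ← (1−pc)·f1 + pc/q`, `f2 ← (1−pc)·f2 + pc/q²`.  This keeps the
marginalization identity `Σ_b f2(i,j,a,b) = f1(i,a)` exact while making
`ln f1` — the fit's initialization — finite for states never observed.  No
pseudocount is prescribed by the method itself; `1e-5` is far below the
0.02 working tolerance and has no measurable effect on anything but the
logarithm's domain.  All container invariants (row sums, block sums,
marginalization, `p_id` normalization, non-negativity) are asserted after
every computation.

## Inference

Starting from the site-independent model `h = ln f1, J = 0, λ = 0` (whose
Boltzmann marginals are exactly `f1`), each iteration:

1. samples `mc_n` sequences from the current model by Metropolis Monte
   Carlo (thinning 1000, burn-in 10·thinning, seed = `seed + iteration`);
2. measures the model's `f1`, `f2`, `p_id`;
3. updates `h ← h + ε_h (f1 − f1^model)`;
4. updates `J` by the four-branch L1 proximal rule: a dormant coupling
   (`J = 0`) stays zero unless its frequency gap exceeds `γ`, in which case
   it activates with the thresholded step `−ε_j (gap − γ·sign(gap))`; an
   active coupling takes the step `J − ε_j·gap − ε_j·γ·sign(J)` and is
   clipped to exactly zero if it crosses sign;
5. updates `λ ← λ + ε_{id} (p_id − p_id^model)`;

and stops when the **maximum absolute mismatch over all three statistic
families** is below `tol = 0.02`.  Because the per-iteration ensemble's
own sampling noise is not far below that tolerance at desk scale, a stop
signaled by the working ensemble is **confirmed on a larger ensemble**
(`confirm_n`, default `4·mc_n`) before the fit is declared converged;
without this, the rule can fire on a lucky noisy iteration and a
subsequent independent convergence report may land just above tolerance.  That tolerance is not arbitrary: it is
the level at which the empirical frequencies themselves stop being
reproducible across subsamples of family-sized alignments, so demanding
more would fit noise.  We apply it to `f2` and `p_id` as well as `f1`,
since `λ` is fitted to `p_id` (the looser reading — `f1` only — would make
the λ update's convergence unobservable).

**Update signs.**  As typeset, the field update reads
`h ← h − ε(f − f^model)`, which under `E = −Σh` moves the model *away* from
the data; we treat this as a transcription artifact and implement all three
updates so that an empirically over-represented statistic becomes more
favorable (h and λ up; J — which enters `E` with a positive sign — down).
The independent-site fixed-point test and the convergence of every fit in
the suite confirm the direction.

**Learning rates.**  No reference values exist.  Near the optimum each
coordinate contracts at roughly `ε · Var(f) ≈ ε · 0.05` per iteration, so
rates of order 0.1 would need thousands of MC iterations; and `λ` must
reach order-10 values through gradients bounded by probability differences
of a few percent, so its rate must be much larger than the others.  The
defaults `ε_h = 0.5`, `ε_j = 2`, `ε_{id} = 5` with geometric decay 0.998
converge on the desk-scale problem in ~10–15 iterations and remain stable
on every toy problem in the suite; all are exposed in `fit_config()`.

**L1 strength.**  `γ = 1e-3` (frequency units) by default: small enough not
to bias the fitted statistics beyond the 0.02 tolerance, large enough to
keep the coupling matrix sparse.  Note a subtlety the test-suite documents:
with `γ` below the Monte Carlo noise floor of the frequency gaps
(`≈ 4·sqrt(f/mc_n)`), dormant couplings activate on noise even when the
true couplings are zero; exact "J stays identically zero" behavior is only
guaranteed for `γ` above that floor, and the independent-site recovery test
uses analytically exact statistics and `γ = 0.05` accordingly.

**Ensemble size.**  The documented production setting is 80000 sequences
per iteration; the package default is the desk-scale 5000, which bounds the
per-iteration gradient noise well below `tol` for `L = 12` and keeps a full
fit around half a minute.  Non-convergence at `max_iters` returns the best
parameters seen with a flagged trace — an inspectable outcome, not an
exception.

## Sampling

Plain Metropolis at temperature 1: propose a point substitution at a
uniform position to a uniform *different* state (the minimal symmetric
proposal consistent with "a point mutation in any position"), accept when
`ΔE ≤ 0`, else with probability `e^{−ΔE}`.  The gap is proposable — it is
one of the `q` states — whereas the `random_sequences()` negative control
excludes gaps by default, since "random amino-acid strings" means residues.
Chains start from a uniform random string; recording every `thin = 1000`
steps after a default burn-in of `10·thin` makes successive records
effectively independent for desk-scale widths.  Exactness is verified
against full enumeration of a 9-state toy model (total-variation distance
< 0.02 at 10⁵ samples).

## Repeat arrays and the decomposition convention

For arrays of `n` repeats only adjacent repeats interact: each repeat
carries an internal energy (fields + intra-repeat couplings) and each
adjacent pair an interface energy (inter-repeat couplings − λ of that
pair's identity).  The **intra-repeat parameter block of the first half is
reused for every repeat**.  Because a concatenated pair evaluates its
second repeat with the *second*-half block, the decomposition total equals
the pair energy exactly only when the parameters are symmetric under repeat
exchange — the regime in which the pair model and the array model describe
the same physics, and the regime in which the test-suite states its exact
identities.  Fitted parameters are near-symmetric (every natural repeat
appears in both halves across the training pairs) but not exactly so; for
mutations whose positions sit in one repeat, the asymmetric contributions
cancel in energy differences.

ddG-proxy prediction scores each mutation set by the array-energy change
and regresses it on the experimental ΔΔG.  Experimental tables must
declare their sign convention per row (`destab_positive` /
`destab_negative`); we align signs from that declaration rather than
guessing an axis convention that is not recoverable from published figure
text.  Structural-disruptor rows (e.g. serine→proline) carry an exclusion
flag: they are scored and tabulated but left out of the linear fit.

Consensus sequences take the per-column argmax over the 20 residues — the
gap is excluded (a consensus is a designable sequence), ties break
alphabetically and therefore deterministically.

## The synthetic world

`generator_spec()` defines the ground-truth families the suite fits:

| parameter | default | why |
|---|---|---|
| `L = 12`, `q = 21` | two repeats of 6, full alphabet | smallest width with a meaningful interface whose `f2` (29106 free joints) is estimable from desk-scale samples |
| `n_sequences = 5000` | alignment size | gradient noise `≈ 4·sqrt(f/n)` stays below the 0.02 tolerance; a fit runs in ~30 s |
| `field_scale = 1` | SD of Gaussian fields | per-column frequencies span ~2–20%, like real profile columns |
| `coupling_density = 0.15`, `coupling_scale = 0.5` | sparse coupled pairs | coupling energy comparable to field energy; sparsity mirrors the 85–91% of couplings the L1 fit zeroes on real families |
| `lambda_profile = "heavy-tail"`, `λ(k) = 10·(k/(L/2))³` | identity potential | boosts only the top identity bins, producing the populated high-identity tail characteristic of consecutive natural repeats; `λ(L/2) ≈ 10` is what it takes for near-identical halves to be visible at all against the ~`0.1^{L/2}` chance baseline |

What the generator does **not** emulate: real amino-acid composition and
biochemistry, phylogenetic correlation between rows (rows are independent
draws), alignment artifacts (mis-detected repeat ends, insertions), and
family-specific structure.  A green fit on this world therefore establishes
that the estimator is *consistent* — it recovers a model in the class it
assumes, to the stated tolerance — not that any particular biological
family satisfies those assumptions.

## Numerical and format choices

* Couplings are stored dense in memory (`(Lq)×(Lq)` symmetric, zero
  same-position blocks) for O(L) Metropolis updates, but serialized sparse
  as `(i, j, a, b, value)` tuples, since most entries are exactly zero
  after an L1 fit.
* All serialization is JSON at 17 significant digits — full-precision,
  text-only, bit-exact on round trip.  (A binary array container would be
  faster for `f2` at ankyrin scale; the desk scale does not need it, and
  text files keep every artifact diffable.)
* Determinism: every stochastic entry point takes a seed; the fit threads
  `seed + iteration` into its sampler calls; the command-line interface
  funnels all randomness through `--seed`.
* Validation failures raise a dedicated condition class, which the CLI maps
  to exit code 2 (vs 1 for unexpected failures).

## Known limitations

* No sequence reweighting (Meff/θ) — redundancy is handled up front by
  clustering representatives instead.
* No pseudolikelihood or mean-field inference backends; the Monte Carlo
  gradient path is the only estimator, and it is the slow-but-faithful one.
* Repeat-end completion against UniProt and PDB-derived contact maps are
  out of scope: inputs are assumed completed, contact maps are consumed as
  plain 0/1 matrices (one can be produced with any structure library by
  thresholding heavy-atom distances between residue pairs).
* The identity potential addresses one specific higher-order correlation;
  families with other long-range structure (e.g. capping repeats) are
  outside the model class.
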