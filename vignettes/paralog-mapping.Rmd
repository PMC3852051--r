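---
title: "Mapping paralogs by units of coevolution: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping paralogs by units of coevolution: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coevomap)
```

## The statistical model

`coevomap` maps members of two protein families *A* and *B* onto each other,
one-to-one and within species, so that mapped pairs look maximally
coevolving. The evidence is purely alignment-based. For two rows of one
family's alignment we count, over the columns where **both** rows carry a
residue, the number of mismatches Δ and the number of comparable columns ℓ
(matches plus mismatches); gap columns are never counted, `.` and `-` are
both gaps, and comparison is case-insensitive on uppercased rows. Ambiguity
codes (X, B, Z) are compared literally: the model is defined on raw
match/mismatch counts, not on substitution chemistry.

Each family is imagined to descend from a common (unobserved) ancestor, and
mismatches between two rows are modeled as independent Bernoulli trials with
a hidden pair-specific substitution rate. If (a,b) and (a′,b′) are two mapped
pairs and the rates on the two sides are equal — the coevolution hypothesis —
then, conditional on ℓ_A, ℓ_B and the total mismatch count Δ_A + Δ_B, the
split (Δ_A, Δ_B) is hypergeometric:

$$f(\Delta_A, \Delta_B) \;=\;
  \frac{\binom{\ell_A}{\Delta_A}\binom{\ell_B}{\Delta_B}}
       {\binom{\ell_A+\ell_B}{\Delta_A+\Delta_B}}.$$

The quadruple ((a,b),(a′,b′)) is a **unit of coevolution** and log *f* is its
score: 0 is attained when both sides are mismatch-free, and strongly unequal
relative divergence drives the score far below 0. The hidden rates themselves
are never estimated — they only motivate the conditional distribution. Units
are treated as independent, so the log likelihood of a matching θ is the sum
of log *f* over all unordered pairs of distinct matching edges; a matching of
size one has likelihood 1 (no units). The per-pair summary
`coevolution_degree()` — the mean unit score over the n−1 units containing a
pair — and the per-matching summary `avg_unit_loglik()` — the likelihood
normalized by the `choose(n, 2)` unit count — make instances of different
size comparable.

The search space is deliberately rigid: the matching graph connects every
same-species pair of members, hence decomposes into complete bipartite
components, and all maximal matchings share the cardinality
n = Σ_t min(|A_t|, |B_t|). Only these maximum-cardinality matchings are
considered. Species present in only one family simply contribute no edges.

## From likelihood to a quadratic program

With binary edge variables the objective is quadratic: a sum of f-scores over
selected edge pairs (i,k), (j,l), indexed with i < j by family-A order and
k ≠ l. Any fixed total order works; we use lexicographic (A index, then B
index). Because all scores are ≤ 0, a cardinality constraint is needed — or
can be traded away: shifting every quadruple score by an offset
K = −min log f + 1 makes all weights strictly positive, upon which every
optimal matching is automatically maximum-cardinality and the shifted
objective, corrected by choose(n,2)·K, equals the log likelihood **exactly**
for every maximum-cardinality matching. `bqp2_objective()` implements the
shifted form and the equality with `log_likelihood()` is asserted across the
test suite on enumerated search spaces. The margin of 1 beyond strict
positivity (`offset_margin`) is arbitrary and harmless: the optimum is
invariant to K.

## The Lagrangian relaxation

The shifted program is the standard quadratic formulation of global network
alignment, and we solve it the same way. Each unit's weight is split in half,
w = (log f + K)/2, and charged to both of its edges. The **local problem** of
edge (i,k) selects a maximum-weight matching among candidate partner edges
(j,l) disjoint from (i,k); the **master problem** selects a maximum-weight,
maximum-cardinality matching over the local profits v_ik. The coupling
constraint — that the two copies of a unit agree — is dualized with one
multiplier λ per oriented quadruple (i < j, k ≠ l, cross-species units
included): the local problem of the first edge sees w + λ, that of the second
w − λ. For **any** λ the master value, minus choose(n,2)·K, is an upper bound
on the optimal log likelihood, and the master matching is itself feasible, so
its true likelihood is a lower bound. This bound sandwich is the package's
central invariant and is tested directly (weak duality on every iteration
trace, and dominance over exact enumeration on small instances).

Multiplier search uses a hybrid scheme:

* **Subgradient steps** (Held–Karp): λ ← λ − t·g with
  t = μ·(best upper − best lower)/‖g‖², where g is +1/−1 on units chosen by
  only one of their two local problems. μ starts at 2 and halves after 20
  consecutive non-improving upper bounds.
* **Dual-descent moves** every 5 iterations: multipliers of violated units
  are shrunk halfway toward the value that equalizes their two oriented local
  profits, and the move is kept **only if it strictly decreases the dual
  bound**. The monotone acceptance test is what makes this a descent scheme;
  an unconditioned shrink can cycle against the subgradient trajectory (we
  observed exactly that during development, which motivated the guard).

Feasible matchings are additionally polished by a deterministic
within-species 2-swap local search (`local_search = TRUE`), which only ever
raises the lower bound and never touches the upper bound. All inner
assignment problems — local, master, rectangular or square — are solved
exactly by an O(n³) shortest-augmenting-path Hungarian routine (in C++), with
ties broken toward the lowest column index, so the entire solver is
deterministic for a fixed configuration; the `seed` in `solver_control()` is
provenance metadata only.

Termination: proven optimality (relative gap ≤ `gap_tol`, default 1e-6),
the iteration cap (default 300), or the wall-clock limit (default 300 s —
bound quality saturates well before that on instances of the sizes we target,
and the marginal return of longer runs is small). The **relative gap** is
(upper − lower)/|lower|, defined as 0 when the bounds agree to 1e-9 and
infinite when lower = 0 with slack remaining. A genuine duality gap is
possible — the relaxation is not exact in general — in which case the solver
returns the best feasible matching with an honest nonzero certificate rather
than a false proof.

## The synthetic generator

`generate_families()` realizes exactly the generative assumptions of the
scoring model, so recovery tests are interpretable. Each family descends from
its own random ancestor on a star phylogeny; sequence v substitutes each
column independently with rate q_v (always to a different residue, uniform
over the 19 alternatives); the planted partner of v in the other family gets
the **same** q_v, so every planted unit satisfies the equal-rates hypothesis
by construction. Within a species, paralog rates are drawn from
`shared_rate_range` (default 0.05–0.75); with `decoy_rate_jitter > 0`
consecutive paralog rates are separated by at least the jitter, which
controls how distinguishable wrong pairings are (jitter 0 draws rates
independently, allowing near-ties). Gaps are inserted per sequence and column
i.i.d. at `indel_rate` (default 0.02) — just enough to exercise the
gap-skipping count rules. Family-B output order is shuffled so the truth is
never positional, and generation is byte-identical given the seed without
disturbing the caller's RNG stream.

Defaults (4 species × 3 paralogs per family, 200 columns, jitter 0.3) are a
strong-signal operating point: rates separated by 0.3 over ~190 comparable
columns give mismatch-count differences many standard deviations wide, and
the solver recovers the planted matching essentially always. What the
generator does **not** emulate: realistic substitution matrices, site-rate
heterogeneity, non-star phylogenies, correlated indels, or alignment error.
Passing recovery tests therefore demonstrate correctness of the inference
machinery under its own model, not performance on real Pfam-style families,
where alignment quality is known to dominate.

## Numerical and design choices

* All scores are computed in log space via `lchoose` (log-gamma); the unit
  score is always finite because the observed split lies inside the
  hypergeometric support, and it is exactly symmetric in its two arguments.
  The implementation is cross-checked against `stats::dhyper` in the tests.
* Degenerate pairs with ℓ = 0 (complementary gaps) are legal: both Δ are
  forced to 0 and the unit contributes log 1 = 0.
* `enumerate_max_matchings()` is the exact oracle over the search space — the
  cross product over species of all injections from the smaller side into
  the larger — and refuses instances beyond `cap` (default 1e6) with a
  pointer to the Lagrangian solver.
* The score table is dense over quadruples; for the target instance sizes
  (tens of edges, thousands of quadruples) this is cheap and keeps the solver
  inner loop vectorized.
* Test and validation problem sizes were chosen so that exact enumeration
  stays trivial: oracle comparisons run on 2–4 species with up to 4
  sequences per family per species (≤ 2·10⁴ matchings), recovery runs on the
  default 4 × 3 configuration at length 200. These are the package's own
  fixture scales, small enough to enumerate yet large enough that wrong
  bound arithmetic cannot hide.

## Limitations

* Only maximum-cardinality matchings are searched. When the biologically
  correct mapping is smaller (unmatched paralogs), forced extra pairings can
  depress the average unit likelihood; allowing smaller matchings would
  require a cardinality-penalized variant of the program.
* One-to-one mappings only; many-to-many interaction patterns are out of
  scope.
* The score uses raw mismatch counts and therefore inherits all alignment
  error; no column weighting or confidence scores are applied.
* The relaxation can leave a nonzero duality gap; the result is then a
  feasible matching with certified bounds, not a proven optimum.
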