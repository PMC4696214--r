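---
title: "State-rich Markov chains for genotype-frequency models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-rich Markov chains for genotype-frequency models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popchain)
```

## The model

`popchain` works with the discrete stochastic model of a fixed-size
population of `N` diploid, partially asexual organisms at one locus
with two alleles `a` and `A`.  A state assigns every individual to one
of the three genotypes, so a state is a count triple
`(n_aa, n_aA, n_AA)` summing to `N`.  The number of states is the
multiset coefficient

$$|S| = \binom{N + g - 1}{N}, \qquad
  g = \prod_{i=1}^{L} \binom{A_i + P - 1}{P},$$

where `g` counts the possible genotypes of an organism of ploidy `P`
at `L` loci with `A_i` alleles each (`g = 3` for the biallelic diploid
case).  Only the biallelic diploid state space is enumerated; richer
configurations are supported through their cardinalities, which are
computed in exact integer arithmetic because realistic configurations
quickly exceed the 2^53 integer range of doubles:

```{r}
state_count(100, 3)
state_count(20, genotype_count(2, c(4, 4)), as = "character")
```

One generation maps a parental state to `N` independent offspring.
Each offspring is, with probability `c` (the clonality rate), a copy
of one uniformly chosen parent, and otherwise the product of random
mating: two gametes drawn at the parental allele frequency.  A
symmetric per-allele mutation rate `mu` acts on every transmitted
allele.  Column `j` of the transition matrix is therefore the
multinomial distribution of `N` draws from the single-offspring
genotype law of state `j`; the matrix is column-stochastic
("left-stochastic"), and for `mu > 0` every entry is positive, making
the chain irreducible and aperiodic with a unique limiting
distribution.

Two reconstruction choices deserve note, since the one-step law admits
variants:

* **Mutation acts in the clonal pathway too** (default).  Pure
  cloning without mutation would freeze genotype frequencies and the
  matrix would lose its everywhere-positive density at `c = 1`;
  applying the per-allele mutation kernel to clonal copies preserves
  irreducibility for every `c` whenever `mu > 0`.  The alternative is
  available as `model_params(..., clonal_mutation = FALSE)`.
* **Sexual offspring are random unions of mutated gametes** drawn at
  the parental allele frequency, i.e. selfing is permitted at rate
  `1/N` as in the classical Wright-Fisher sampling scheme.

The multinomial probabilities are evaluated in log space
(`lgamma`-based log-factorials) so that columns remain accurate for
populations up to `N ~ 1000` per column; the dense matrix itself is
materialized only up to a capacity guard (`max_states`, default 6000
states), beyond which the column generator
(`transition_column_generator()`) serves columns on demand.

## Sparse approximation

Dense transition matrices cost `|S|^2` doubles, which is the limiting
resource of state-rich chains.  `approximate_matrix()` substitutes a
sparse matrix while preserving the properties the Markov analysis
relies on.  Per column (threshold `s`, the minimal probability mass
retained):

1. rank the entries by decreasing value, ties broken by ascending row
   index (a stable ranking);
2. find the minimal rank `r` whose cumulative sum reaches `s`;
3. raise `r` to at least 2 (always keep the two biggest values);
4. extend `r` across any run of values tied with the `r`-th;
5. zero everything ranked beyond `r` **except** the main diagonal and
   the wrapped first sub-/super-diagonal
   (`(i-1, i, i+1) mod |S|`); entries that were zero in the original
   are never created;
6. rescale the column to sum to one.

The kept diagonal preserves aperiodicity; the wrapped sub-/super-
diagonal forms a Hamiltonian cycle through all states and guarantees
irreducibility.  The wrap-around is a structural device: the wrapped
neighbours are not biologically adjacent states, they merely keep the
graph strongly connected.  Discarded mass per column is at most
`1 - s` before rescaling, so the total pre-rescaling perturbation is
bounded by `(1 - s) |S|`; after rescaling the per-column L1
perturbation is bounded by `2 (1 - s)`.  Both bounds are asserted in
the test suite; the bound is stated for the pre-rescaling matrix
because the two sides of step 6 obey different constants.

Fed with a column generator the algorithm is streaming: peak memory is
the sparse result plus a single column.

## Limiting distribution and first-passage times

The limiting distribution is the normalized right eigenvector `v` with
`M v = v`.  The default solver is a direct linear solve of the
singular system `(M - I) v = 0` with one equation exchanged for the
normalization (dense storage) or with one state grounded (sparse
storage, which keeps the LU factors sparse).  A direct solve was
chosen deliberately: at mutation rates around `1e-6` the subdominant
eigenvalue lies within `~1e-6` of one, so plain power iteration needs
on the order of the inverse gap (millions) of iterations to resolve
the eigenvector; an LU solve is exact up to round-off in one pass and
is deterministic.  Power iteration remains available
(`method = "power"`) and doubles as an independent cross-check on
well-gapped matrices in the tests.  Every returned vector must pass
the residual check `sum(abs(M v - v)) < 1e-8`, so reducible inputs
(e.g. `mu = 0`, where the fixation states are absorbing) are refused
with an error rather than silently returning one of many invariant
vectors.

Expected first-passage times to a target set solve
`t (I - M') = 1` over the non-target sub-matrix `M'` (column
convention); target states have time exactly zero.  The solve is
direct, with a positivity/finiteness check standing in for a
reachability analysis.

## Network summaries

The matrix is read as a weighted directed graph (edge `j -> i` with
probability `M[i, j]`).  The toolkit computes:

* **most probable neighbours** — per-column argmax, all ties reported,
  optionally excluding the self-loop (both behaviours are provided
  because near-absorbing states are their own best successor);
* **most probable paths** — Dijkstra on `-log` transformed weights;
  zero entries (possible after approximation) are treated as absent
  edges, not infinite costs;
* **flow threshold** — the bottleneck probability of the most
  probable path, with `filter_edges()` as the percolation companion;
* **betweenness** — the count, per state, of most probable paths
  (one per ordered pair) passing through it as an interior node;
* **per-state probabilities** — `p_stay`, `p_out`, `p_in`,
  `p_in_inf`, `p_inf` and raw column access `p(i | j)`.

Tie-breaking is deterministic and documented: the Dijkstra frontier
pops equal-cost nodes in ascending index order and an equal-cost
relaxation keeps the earlier-indexed predecessor.  This yields one
well-defined winner per ordered pair (which is what the betweenness
counts require); it is not guaranteed to be the lexicographically
smallest of all tied optimal sequences, a distinction without
consequence for generic (tie-free) weights.

## F_IS distributions and divergences

Per state, the inbreeding coefficient is
`F_IS = 1 - nu_aA / (2 nu_a nu_A)`; it is undefined at monomorphic
states.  `fis_distribution()` aggregates limiting-distribution mass by
the *exact* rational value of `F_IS` (classes are reduced fractions,
not floating-point bins; binning is left to display layers).  Mass on
monomorphic states is tracked separately as `undefined_mass` and never
enters divergence computations — mirroring the omission of infinite
values from the test statistic — and the remaining class masses are
deliberately *not* renormalized, so divergences compare the
distributions as they stand, fixation mass excluded.

Divergences: total distance (`sum |f - g|`), Kullback-Leibler
(`0 log 0 = 0`, infinite terms omitted), the power-divergence family
(default `lambda = 2/3`, the conventional compromise member), and the
Kolmogorov-Smirnov statistic over sorted classes.  The G-test scales
probabilities by a pseudo-count `n_eff` (default 1000, exposed as an
option since the comparison is qualitative); classes with
`g = 0 < f` are dropped and counted as omitted.

A practical caveat the package's own numbers make explicit: at
mutation rates around `1e-6` the limiting distribution concentrates
(>99.7% at `N = 100`) on the two monomorphic states, so the
*unconditional* F_IS contrast between modest clonality rates (c = 0
vs 0.1) is of order `1e-5` — smaller than the approximation-induced
distance at `s = 0.9` (order `1e-3`).  Threshold adequacy must
therefore be judged against the contrast actually of interest, by
exactly the comparison `scripts/acceptance.R` performs; a single
global `s` cannot be assumed to preserve arbitrarily fine contrasts.

## Morris screening

`run_gsa()` screens the approximation quality over the four model
parameters with Morris one-step-at-a-time trajectories.  Defaults
follow the study design: grids `N = 10, 20, ..., 100`;
`mu = 1e-12, 1e-11, ..., 1e-3` (uniform on the exponent);
`c = 0.1, ..., 1.0`; `s = 0.80, 0.82, ..., 0.98`; and `r = 30`
trajectories of `k + 1 = 5` points, i.e. 150 model evaluations — the
reading of "150 Morris samples" as evaluations, since `r(k+1) = 150`
matches that count exactly; `r` is a free argument for the other
reading.  Parameters are normalized to `[0, 1]` on their grid index
(so `mu` steps are uniform in `log10`), the elementary effect of a
step is the normalized finite difference, and `mu*` / `sigma` are the
mean absolute value and standard deviation of the effects per
parameter.  Non-finite outputs are omitted from the aggregation;
per-point failures are recorded, flagged and skipped rather than
fatal.  All randomness flows through the single `seed` argument and
designs are exactly reproducible.

Recorded outputs per design point: sparse density, the four
divergences between original and approximate limiting F_IS
distributions, and the G-test p-value.

## Synthetic data and test design

The package needs no external data: the model *is* the generator, and
`make_fixture()` supplies the deterministic toys (fixed 3x3 and 5x5
chains, seeded strictly positive random matrices, small model
matrices) used across the test suite.  The study conditions exercised
by the tests are the published ones — `mu = 1e-6`, `c ∈ {0, 0.1}`,
`N ∈ {5, 20, 100}`, `s ∈ {0.8, 0.9, 0.99}`.  The full screening
design (N up to 100, 150 evaluations) is expensive on one CPU, so the
routinely-run screening uses `N ≤ 30` with `r = 5`; this is a
package choice of problem size for routine verification, with the full
design available through `run_gsa()` defaults.

What the toys do *not* emulate: multi-locus or polyploid dynamics
(only their state-space cardinalities are supported), selection,
migration, asymmetric mutation, or varying population size.  Passing
tests therefore certify the algorithms on the biallelic diploid
partial-clonality chain and on generic column-stochastic matrices, not
those extensions.

## Numerical choices, in one place

* Column-stochasticity tolerance: 1e-12 internally; file input warns
  at 1e-6 and fails at 1e-3.
* Eigenvector residual tolerance 1e-8 (L1); direct solve as default,
  power-iteration cap `1e6` with L1-change stop `1e-13`.
* Approximation: ranking ties by ascending row index; wrapped
  diagonals implemented literally (`mod |S|`); zero originals never
  re-created.
* Dijkstra: costs `-log p`, non-negative; deterministic index-order
  tie-breaking; self-loops never interior.
* F_IS classes: exact reduced fractions; undefined mass separate.
* Exact big-integer arithmetic (base-1e7 limbs) for cardinalities;
  numeric return refuses values above 2^53 rather than rounding.

## Known limitations

* Dense materialization is limited by memory (`|S|^2` doubles); the
  generator pathway lifts the build, but the dense eigenvector solve
  still requires the materialized matrix.
* Lumping-based exact state aggregation and external-memory paging are
  out of scope.
* The G-test's `n_eff` has no canonical value; conclusions should not
  hinge on its magnitude.
* At extreme grid corners (e.g. `mu = 1e-12`) the spectral gap
  approaches round-off and limiting-distribution details beyond the
  fixation masses carry reduced accuracy, though residual checks still
  hold.
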