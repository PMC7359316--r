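---
title: "Stacked forests and combinatorial G-by-E interaction detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked forests and combinatorial G-by-E interaction detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossgxe)
```

## The problem

Commercial hybrid maize breeding crosses inbred lines against tester lines
and measures progeny yield across many locations and years. A program of a
few hundred parents per pool observes only a sliver of the possible
hybrid-by-environment grid — often well under 0.1% — yet breeders must rank
*all* potential crosses, including those never planted. Two signals matter:
additive parent and environment effects, which standard models capture well,
and genotype-by-environment (G×E) interactions — yield shifts that occur
only when specific genotype features meet specific environments — which most
black-box learners capture poorly and, worse, cannot *report*.

`crossgxe` implements a three-component stacked predictor for this setting:

1. **RF1** — a bagged regression forest on the one-hot design `X`
   (inbred, tester, inbred cluster, tester cluster, location, year),
2. **a combinatorial G×E interaction model** — a linear model whose
   interaction terms are *learned set-membership columns*, and
3. **RF2** — a second forest on the membership matrix `Z`, trained on RF1's
   out-of-bag residuals.

The final prediction is the sum of the two forest outputs. The interaction
model in the middle is the scientific contribution: it yields an explicit,
human-readable list of which variable combinations move yield and by how
much.

## The interaction model

Write the aggregated trial table as an \(n \times p\) binary matrix \(X\)
(one-hot blocks, one 1 per block per row) and yields \(y\). The model is

\[
\hat y_i = \beta_0 + \sum_{j=1}^{p} X_{ij}\beta_j + \sum_{k=1}^{K} b_k Z_{ik},
\]

where each interaction \(k\) is encoded by a pattern vector
\(\alpha_k \in \{0, 0.5, 1\}^p\): the value 0.5 marks a variable as not
involved, while 0 or 1 requires the variable to take that value. Observation
\(i\) *receives* interaction \(k\) — \(Z_{ik} = 1\) — exactly when
\(X_{ij} + \alpha_{kj} \neq 1\) for every \(j\), i.e. when every non-neutral
requirement is met. The *order* of a pattern is its number of non-neutral
entries; order-2 and order-3 patterns are the biologically reportable range.

Given the pattern matrix, \(Z\) is determined and the model is an ordinary
linear regression in \([\,1 \mid X \mid Z\,]\). One-hot blocks are exactly
collinear with the intercept, so the system is rank deficient on any roster
design; `fit_gxe()` therefore returns the **minimum-norm least-squares**
solution via the SVD pseudoinverse rather than dropping reference levels.
This keeps full-rank toy examples exact (every coefficient recovered to
machine precision) while real rosters remain fittable, and it is invariant
to column order.

```{r figure2}
fx <- figure2_fixture()
fit <- fit_gxe(fx$X, fx$y, fx$truth$alpha)
tidy(fit)
```

The built-in eight-plant fixture has three binary variables (high-yield
gene, fertile soil, wet weather), noiseless yields, and three planted
order-2 interactions; the fixed-pattern fit recovers the baseline 2,
additive effects (1, 0, 2) and interaction effects (−1, +1, +2) exactly,
with zero residual.

## Searching for patterns

The pattern space is astronomically large (\(3^p\) per slot), so patterns
are found by a greedy forward heuristic with local search
(`search_interactions()`):

* **Seeding.** Each restart starts from the variable pair whose elementwise
  product has maximal absolute covariance with the current residual (the
  next-best pair for the next restart, and so on), with the required values
  chosen the same way. For binary columns all pair scores reduce to two
  matrix crossproducts, so seeding is cheap and deterministic.
* **Refinement.** Steepest-descent coordinate search: every
  single-coordinate move (any position to any other value in
  \(\{0, 0.5, 1\}\), respecting `max_order`) is scored in one batched
  linear-algebra pass, and the best move is applied until none improves.
  Taking the *best* move rather than the first improving one matters on
  sparse rosters: many small chance improvements (e.g. excluding one inbred
  from a member set) compete with the single large move that completes a
  real cluster-by-environment pattern, and first-improvement search fills
  the order budget with noise before finding it.
* **Acceptance.** A refined pattern joins the model only if the acceptance
  score improves by a relative `tol` (default `1e-6`). The score has two
  keys: the mean validation SSE over `inner_k` internal folds (primary —
  it may never get worse), and the training SSE (tie-breaker). The search
  stops at `max_K` or at the first rejected round.

Two scoring regimes are deliberate. With `inner_k >= 2` the internal
cross-validation guards against overfitting — an order-\(n\) pattern can
zero out any single residual, and CV is what stops such patterns. With
`inner_k = 1` no split is made and candidates are scored on training SSE.
The second regime exists because leave-few-out validation of a
near-interpolating model is meaningless at tiny \(n\): on the eight-plant
example, *every* extension beyond one pattern worsens leave-one-out SSE
(verifiable by exhaustive enumeration), yet the data are noiseless and the
exact three-pattern solution is the right answer. Small noiseless designs —
the worked example, oracle-comparison studies — should use `inner_k = 1`;
realistic noisy rosters should keep the default five folds.

Candidate evaluation shares, per fold, a truncated SVD of the additive
design \([\,1 \mid X\,]\); scoring a candidate then costs one projection of
its membership column plus a \((K{+}1)\)-dimensional solve, batched across
candidates into single BLAS calls. A brute-force enumerator
(`brute_force_search()`, \(p \le 12\), \(K \le 2\)) provides an independent
optimality oracle: on noiseless planted order-2 data the heuristic attains
the enumerated optimum, and it can never beat it.

Patterns are identifiable only up to linear reparameterization: with free
additive terms, requiring `x2 = 0` with effect \(-b\) plus an additive shift
is exactly equivalent to requiring `x2 = 1` with effect \(+b\). Recovery is
therefore judged on the *signature* — the set of involved variables — not on
the required values, and the worked example is asserted on its residual, not
on pattern identity.

## The stack

`fit_stacked()` runs the pipeline: aggregate replicate plots (arithmetic
mean per unique combination), one-hot encode, fit RF1, search for patterns
on the same \((X, y)\), build \(Z\), and fit RF2 on \(Z\) against
\(y - \hat y_1^{\text{oob}}\). Out-of-bag (not in-sample) first-stage
residuals are the second-stage response: in-sample forest residuals are
shrunk nearly to zero and carry no signal, while out-of-bag residuals are
unbiased estimates of what RF1 misses. If the search accepts no patterns,
RF2 degenerates to the mean residual and the stack equals RF1 plus a
constant.

The forests are delegated to `ranger` (bootstrap bagging, per-split feature
sampling, node-size control, OOB predictions), pinned to one thread and an
explicit seed so fits are bit-reproducible. Production-scale defaults are
1000 trees, node size 10, and 100 features per split for RF1 and 20
(clamped to \(K\)) for RF2. RF2 sees \(Z\) alone by default — its job is the
interaction structure — though `rf2_include_X = TRUE` widens it to
\([Z \mid X]\).

## Synthetic trials

Real multi-environment trial data of this shape is proprietary, so
`simulate_trials()` generates rosters with known ground truth. Defaults
describe a desk-scale program: 50 inbreds and 40 testers in 5 and 4 genetic
clusters, 20 locations, 3 years, 2% of the hybrid-location-year grid
observed, and 1–2 replicate plots per cell. Yields come from additive
parent, cluster, location and year effects (parent effect sd 1, cluster
0.3, location 0.8, year 0.4 before rescaling), two planted interaction
patterns of order 2–3 with effects of ±2 parent-sd, and Gaussian plot noise
(sd 0.6), then are affinely rescaled to mean 1.0 and sd 0.1 — the
anonymized scale on which such data is released. Planted patterns live on
cluster and environment columns, not parent ids: an id-level pattern would
touch a handful of plots at realistic sparsity and carry no recoverable
signal, and cluster-by-environment is the level at which G×E is reported.

What the generator does *not* emulate: spatial field trends and plot
autocorrelation, location geography, genetic relatedness beyond flat
cluster membership, year-to-year genetic trend, and unbalanced replication
by entry importance. Passing tests on this generator therefore demonstrate
the machinery — encoding, search, stacking, ranking — under a known truth,
not performance on any particular commercial dataset.

## Evaluation and ranking

`cross_validate()` runs outer \(k\)-fold CV (default tenfold) over the
aggregated table, with optional inner fivefold grid search for forest
hyperparameters restricted to the outer training rows; train/validation
index disjointness is asserted at every level. `cv_compare_stacked()` fits
RF1 once per fold and reuses it in both arms, isolating the contribution of
the interaction stages. Metrics are RMSE, MAE and \(R^2\) (undefined and
reported `NA` for a zero-variance response).

`cross_grid()` predicts every inbred-by-tester pair averaged over all
location-by-year cells (refusing grids beyond \(10^7\) cells unless
overridden); `rank_parents()` averages predictions per parent, forms
top/bottom lists of size \(\lfloor q \cdot \text{count} \rfloor\) (at least
one; at \(q = 0.05\), 29 of 593 inbreds and 24 of 496 testers), and counts
their overlap with observation-ranked lists. `cluster_summary()` reports
mean predicted and observed yield per genetic cluster.

## Numerical choices and problem sizes

* Rank decisions in all pseudoinverse solves truncate singular values at
  `max(dim) * .Machine$double.eps * max(d)`.
* Local-search ties prefer the neutral 0.5 (simpler pattern), then the
  lower value, then the lower position.
* `max_order` defaults to 4: reportable interactions are two- and
  three-way, and unbounded order drives membership columns toward
  single-observation indicators.
* Every stochastic step (fold assignment, forest bootstrap, generator)
  takes an explicit integer seed; repeated runs are bit-identical.
* The package's own evaluation studies run at desk scale: the default
  generator roster (~2,400 observed cells), tenfold outer CV, five seeds,
  forests at 100 trees with per-split features 30 (stage 1) and 20
  (stage 2), search capped at `max_K = 3` with 2 restarts. At these sizes
  the stacked model's mean validation RMSE is consistently below the
  RF1-only baseline on data with planted interactions, mirroring the
  intended production behaviour; recovery studies use \(n = 2000\),
  \(p = 30\) binary designs with two planted patterns at five times the
  noise sd.

## Known limitations

* The heuristic is a local search: it can miss patterns whose pairwise
  seeds are masked by stronger residual structure, and it recovers
  signatures, not the (non-identifiable) required-value encodings.
* On one-hot rosters the search sometimes augments a true pattern with
  complement-coded same-block constraints or small chance constraints;
  these pass the validation guard because they do reduce out-of-sample
  error slightly, but they blur the reported signature.
* Least-squares effect estimates carry no significance measure; the model
  reports magnitudes and memberships only.
* Parents absent from the training roster cannot be predicted (no
  relatedness model), and unseen labels are an error by design.
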