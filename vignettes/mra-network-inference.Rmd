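---
title: "Inferring regulatory networks from perturbation screens with modular response analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory networks from perturbation screens with modular response analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mranet)
```

## The inference problem

Systematic perturbation screens — shRNA knockdowns or CRISPR/Cas9 knockouts
of every gene in a panel, each followed by an expression readout of the whole
panel — are among the most informative data for reverse engineering gene
regulatory networks. Modular response analysis (MRA) is the modeling
framework designed for exactly this design: it assumes the system of `n`
modules (here, genes measured by their transcript abundance) obeys some
unknown smooth dynamics `dx/dt = f(x, p)` with one intrinsic parameter per
module, that measurements are taken at steady state, and that each
experimental perturbation touches exactly one module's parameter. Under
those assumptions the *observable* global responses determine the *direct*
local interactions by linear algebra alone — `f` itself never needs to be
known.

Two matrices carry the analysis:

* the **global response matrix** `R`, where `R[i, k]` is the relative
  steady-state change of gene `i` when gene `k` is perturbed — what the
  screen measures, including all indirect effects propagated through the
  network;
* the **local response matrix** `r`, where `r[i, j]` is the direct, signed
  influence of gene `j` on gene `i` net of network propagation, with the
  normalization `r[i, i] = -1`. This is the inferred regulatory network:
  positive entries are activations, negative entries inhibitions.

They are linked through the steady-state relation `r %*% R = -P`, where `P`
is the diagonal matrix of perturbation sensitivities
(`P[i, i]` = sensitivity of gene `i` to its own parameter times the relative
parameter change; only the product is identifiable, and the package never
attempts to separate the factors).

## Estimating R

On abundance data the package uses the bounded symmetric estimator

```
R[i, k] = 2 * (x_i_perturbed - x_i_basal) / (x_i_perturbed + x_i_basal)
```

which lives in [-2, 2] (a full knockout of a silent-at-baseline gene gives
-2) and degrades gracefully for small denominators. For consensus
signatures already on a signed z-score scale, the denominator is replaced
by `|x_i_perturbed| + |x_i_basal|`, which cannot vanish for small values of
opposite signs. In both estimators a 0/0 cell is defined to be 0: a change
that is unobservable in either condition is treated as no change, the
continuity limit of the formula. The plain relative difference
`(x' - x)/x` is available as `estimator = "relative"`; it is the textbook
definition of the response coefficient and is exact on linear kinetics at
any perturbation strength, but it amplifies noise near zero baselines,
which is why the bounded estimator is the default. Replicates are handled
by averaging `R` matrices (one per plate/replicate batch) rather than
averaging raw expression — `average_response()`.

## Solving for r: inversion vs. blockwise LU

With `r[i, i] = -1` fixed, `r = -[diag(R^-1)]^-1 R^-1` solves the system in
one shot (`solve_local_inverse()`). Inverting `R` is, however, both slower
and numerically weaker than factorization, and it is monolithic. The
package therefore also implements the observation that the homogeneous
steady-state relations split into `n` *independent* linear systems of
dimension `n - 1`: for each target gene `i`, the unknown row
`{r[i, j], j != i}` satisfies one equation per perturbation `k != i`.
`solve_local_blockwise()` solves each subsystem by LU with partial
pivoting and can dispatch them to forked workers. Two contracts matter:

* **Determinism.** The subsystems are embarrassingly independent and
  results are reduced in fixed row order, so the output is bit-identical
  for any worker count. The test suite asserts `identical()` between
  1-worker and 4-worker runs.
* **Failure is loud.** A singular subsystem (e.g. a duplicated response
  column) raises an error naming the offending row; the inverse solver
  refuses matrices whose 1-norm condition estimate exceeds a configurable
  cap (default `1e12`) instead of silently regularizing. A ridge term
  exists for exploration but is off by default — the estimator itself is
  never regularized.

The solver attaches diagnostics (condition estimate, count of
poorly-pivoted subsystems, per-subsystem residuals). After solving, the
diagonal is overwritten with exactly -1: it is a definition, not an
estimate, so floating-point drift is not allowed to leak into downstream
scoring. The sensitivities, when wanted, come from
`recover_sensitivities()`, i.e. `P = -diag(r %*% R)` — the only sign
convention under which `rR = -P`, the inverse formula, and the recovery
formula are mutually consistent.

## Pruning with signed CLR

In a large system most genes do not directly regulate most others, so raw
`r` must be thresholded. Because rows and columns of `r` live on different
scales, a fixed threshold is a blunt instrument. `clr_signed()` adapts the
CLR (context likelihood of relatedness) background correction to signed
interaction strengths: each entry is z-scored against its full row and its
full column (sample standard deviation; the -1 diagonal is part of the
background), the two z-scores are combined as a root sum of squares, and
the sign of the underlying `r` entry is re-attached. Two deliberate
choices:

* **No `max(0, z)` clamp by default.** The MI flavour of CLR clamps
  negative z-scores; for signed local responses a below-background entry is
  informative, so the adapted scheme keeps it. The clamped variant is
  available behind a flag for anyone wanting the strict MI-CLR behaviour.
* **Zero-variance backgrounds contribute `z = 0`** rather than infinities,
  the natural clamping limit for a degenerate row or column.

## Uniform edge selection

All algorithms are compared under one selection protocol: scores are folded
to unordered pairs by `max(|M[i, j]|, |M[j, i]|)` (evaluation references are
undirected and unsigned, so direction cannot be scored), the diagonal is
excluded (it is a normalization constant, not an inference), and the top
`x%` of the full `n(n-1)/2` pair universe is retained —
`ceiling(fraction * universe)` pairs, with deterministic tie-breaking
(score descending, then identifier pair lexicographically) so that top-x%
sets are reproducible. The fraction is taken of the pair universe, not of
an algorithm's nonzero support, which keeps selections the same size across
algorithms; an algorithm with too few nonzero scores (ARACNE after heavy
DPI pruning, typically) is flagged as a shortfall and skipped at that
level rather than padded.

## The MI baselines

The comparison algorithms are reimplemented from their defining formulas:

* **MI matrix** — plug-in (maximum-likelihood) entropies in nats over
  discretized expression, `MI = H(X_i) + H(X_j) - H(X_i, X_j)`.
  Discretization defaults to equal-frequency binning with
  `ceiling(sqrt(m))` bins for `m` samples — the standard heuristic; both
  the bin count and an equal-width alternative are exposed, since the
  choice is a genuine degree of freedom of these estimators.
* **CLR** — row/column z-scores of MI clamped at zero, root-sum-of-squares
  combination; the diagonal (self-entropy) is excluded from the background
  statistics so it cannot dominate them.
* **MRNET** — per-target greedy maximum-relevance minimum-redundancy
  forward selection: relevance `MI[i, j]` minus mean redundancy with
  already-selected genes, stop at the first non-positive score, edge scored
  at selection time, symmetrized by max. The literature sketches this
  strategy without fixing every detail; this concrete scheme is the
  standard MRMR reading and is documented as such.
* **ARACNE** — common threshold `tau`, then the data processing
  inequality: in every triplet with three nonzero MI values the strictly
  weakest edge is removed (`eps` widens "weakest" to a tolerance). All
  triplet decisions are computed on the input matrix and applied at once;
  a cascading variant would depend on enumeration order and so is not
  used. With `eps = 0` a three-way tie removes nothing, since no edge is
  strictly weakest.

When the baselines run inside `compare_algorithms()`, their sample set is
the perturbation panel itself (basal plus all perturbed profiles), matching
how such screens are fed to co-expression methods.

## The simulator: what it emulates, and what it does not

`generate_topology()` builds ground-truth networks in the TF/TA style of
steady-state expression simulators: a block of regulator genes (TFs) that
may control any gene including each other (feedback allowed), and a block
of pure targets (TAs) with no outgoing edges. Edges draw uniform weight
magnitudes in [0.5, 1.5], activating with probability 0.7 — an
activator-rich mix typical of transcriptional regulation. Degradation
rates are uniform in [0.5, 1.5] and basal steady states uniform in [1, 3],
with synthesis rates back-solved from the topology; the weight matrix is
shrunk geometrically until the linear operator has spectral abscissa at
most -0.05 (a stable steady state provably exists) and all synthesis rates
are positive. Everything is seeded, and generators restore the caller's
RNG state.

Perturbations scale one gene's synthesis by `1 - strength`: `strength = 1`
emulates a CRISPR-style full knockout, small strengths an shRNA-style
knockdown. Readouts can carry multiplicative log-normal noise (mean 1) and
are floored at zero, since abundances cannot be negative — the floor only
engages at large strengths, where linear kinetics can overshoot below zero
for strongly inhibited genes.

Two kinetic modes are provided. The linear mode (`dx/dt = b + Wx - Dx`)
has closed-form steady states and a closed-form local response matrix
(`true_local_response()`: `r[i, j] = W[i, j] x_j / (d_i x_i)`), making it
the reference for exactness claims. The hill mode modulates synthesis with
saturating Hill terms (coefficient 2, threshold at half the unregulated
maximum, activator floor 0.1) and integrates with `deSolve::lsoda` until
`max |dx/dt| < 1e-10`; it exists to exercise the pipeline on saturating,
strictly positive kinetics, not to claim biological calibration.

What the simulator does *not* emulate: hallmark-gene imputation and
consensus-signature construction of large screening platforms, off-target
effects, batch structure, or realistic noise covariance. Passing tests on
these simulations therefore demonstrate correctness of the algebra and
sound relative behaviour of the algorithms under clean, stationary
conditions — not performance on any particular experimental platform.

`linear_mra_instance()` is sharper still: it *constructs* `(r_true,
P_true)` and returns `R = -r_true^{-1} P_true`, so `rR = -P` holds by
construction and any correct solver must reproduce `r_true` to round-off.
These instances back the exact-recovery tests up to `n = 938`, the largest
single-screen matrix scale the method targets.

## Evaluation

`confusion_table()` scores a selected edge set against a reference network
over the universe of all `n(n-1)/2` unordered pairs: TP/FP/FN/TN plus
specificity, accuracy, precision, recall — all coupled once the selection
size is fixed — and a hypergeometric enrichment p-value
(`P(X >= overlap)`, upper tail including the observed overlap; the
enrichment convention). Reference scores on a 0–1000 integer scale are
auto-detected and rescaled to [0, 1]; `filter_reference()` supports the
usual strictly-greater thresholds (`> 0`, `> 0.5` by default, `> 0.8`).
All evaluation is undirected: interaction databases and MI methods carry
neither direction nor sign, so directed inferences are folded to pairs
first.

## Numerical and design notes

* Problem sizes in the test suite: exact recovery to `n = 500` (25 seeded
  instances), solver equivalence to `n = 938`, algorithm comparisons on
  100-gene networks over 10 seeds, strength sweeps over
  {0.01, 0.05, 0.2, 0.5, 1} × 5 seeds. These sizes exercise every
  scaling regime of the blockwise solver while keeping a full run in a few
  minutes on a laptop.
* The symmetric response estimator carries an O(strength) bias relative to
  the true local responses even without noise (at strength 0.05 the
  entrywise error is a few percent); the plain relative estimator is exact
  on linear kinetics. This is measurable with
  `global_response(..., estimator = ...)` and is the reason the error in
  the strength sweep rises smoothly: strong perturbations — full knockouts
  in particular — leave the linearization regime in which MRA is safe,
  while the inference remains useful for edge *ranking* well beyond the
  regime where it is numerically exact.
* Perturbation magnitudes are never needed: only steady states enter the
  estimators, so datasets do not store them.
* The hypergeometric tail, multiple solvers, and all generators are exact
  or seeded; the package contains no uncontrolled randomness.

## Limitations

Direction and sign of inferred interactions are discarded at evaluation
time (references are undirected), although the edge lists preserve them.
No confidence intervals on `r` are provided. MI estimation is plug-in
only — no kernel or shrinkage estimators. The simulator's kinetics are
deliberately simple; conclusions about algorithm ordering on real screens
should rest on real references, not on these simulations alone.
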