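---
title: "Inferring clone-level mutability landscapes from mutation trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring clone-level mutability landscapes from mutation trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonerate)
```

## The model

Single-cell sequencing of a tumor is commonly summarized as a *mutation
tree*: a rooted tree whose non-root nodes are mutation events, with each
sampled subclone's genotype given by the mutations on its root path.  The
tree fixes the order of mutations along every root-to-leaf path but says
nothing about the relative order of *siblings* — polytomies are the rule in
tumor trees, because most subclones sit at the same small mutational
distance from their parent.

`clonerate` treats the tree as the outcome of a timed branching process.
Every subclone `i` carries a mutation rate `theta_i` (events per unit time);
once born at time `t_i`, it acquires further mutations, each founding a new
child subclone, until a common sampling time `H` (ultrametric sampling; the
root is born at `t = 0`).  Fixing, for every node `i`, a birth order
`sigma_i` of its children turns the mutation tree into a timed binary
phylogeny.  Along the lineage of clone `i` the model assigns

* to each branch between consecutive birth events of length `dt`:
  density `theta_i^2 * dt * exp(-theta_i * dt)` (a shape-2 Erlang),
* to the terminal branch from the last event to sampling:
  `theta_i * exp(-theta_i * (H - t_last))`.

The joint log-likelihood collapses to

```
L(theta, t, H, sigma) = sum_i theta_i t_i
                      + sum_i sum_j log(t_{sigma_i,j} - t_{sigma_i,j-1})
                      - H * sum_i theta_i
                      + sum_i (2 d_i + 1) log(theta_i)
```

with `t_{sigma_i,0} = t_i` and `d_i` the outdegree of node `i`
(`tree_log_lik()`; the identity with the branch-product form is a tested
invariant).  The estimation problem is to maximize `L` jointly over rates,
times, the sampling time, and the ordering family — the fitted rates are the
tumor's *mutability landscape*, the mutation-rate analog of a fitness
landscape, defined on subclones rather than genes so that epistatic effects
of mutation combinations are visible.

A modelling caveat that matters for interpretation: for a Poisson process
the inter-event gaps are exponential, while the internal-branch density
above is Erlang-2 (mean gap `2/theta` rather than `1/theta`).  We implement
the densities exactly as stated; the consequences for absolute time
calibration are discussed under *Known limitations*.

## Event-time optimization

For fixed rates and orderings, maximizing `L` over `(t, H)` is a concave
program: the objective is linear plus logs of affine gap terms, and all
constraints are linear.  `optimize_times()` solves it with an
interior-point Newton method (exact gradients and Hessians, log-barrier
continuation), started from a strictly feasible point obtained by
Bellman–Ford on the difference-constraint system, and finished by an
active-set equality-constrained Newton polish — optima routinely lie on
constraint boundaries, `H` in particular is always pinned from below.  On
star trees the solution has a closed form via the stationarity conditions
(`star_optimal_times()`), which doubles as an analytic oracle in the tests;
agreement is at 1e-6 or better.

The constraint set couples timing to the feasible rate box
`[theta_min, theta_max]`:

```
d_i / theta_max  <=  H - t_i  <=  d_i / theta_min      (internal nodes)
0 <= t_i <= H                                          (leaves)
```

so that the EM rate update (below) stays inside the box.  Taken literally,
the two-sided band is often *jointly infeasible*: a parent must be born
before its child, hence have the larger exposure `H - t`, which forces
`d_child < d_parent * theta_max / theta_min`; realistic trees violate this
constantly (a one-child node whose child has three children, say).  Our
resolution, a deliberate design choice: the lower band is always enforced
(it bounds the rate update by `theta_max` and anchors `H`), and each node's
upper band is relaxed *minimally* — raised, with 5% headroom, to the largest
lower band among the events forced after it (its descendants and, given the
sibling order, the subtrees of its later siblings).  This keeps every
ordering family feasible while retaining as much of the exposure cap as the
tree allows.  `bands = "lower"` and `bands = "none"` are available for
sensitivity analysis.

## Resolving polytomies

`best_orderings()` runs bottom-up over the tree: each node's children keep
the subtree orderings chosen below them, and the node's own permutation is
selected.  Two scoring tiers:

* **exact** — while `d! * subtree_size` stays within `exact_budget`
  (default 600), every permutation is scored by a full convex solve on the
  node's subtree with a free subtree horizon.  The bottom-up reuse of
  subtree optima is justified by the large-horizon separability of the
  likelihood, and is validated against full enumeration
  (`brute_force_orderings()`) as a tested invariant.
* **heuristic** — for wide polytomies, the large-horizon expansion of a
  subtree's value function is linear-minus-logarithmic in the horizon, with
  linear coefficient equal to the subtree's non-root rate sum; substituting
  it into the parent's problem cancels the subtree structure and leaves
  exactly the star problem in the child's *own* rate, whose optimum is the
  ascending-rate order.  We
  therefore seed with children ordered by descending exposure need (the
  largest lower band in each child's subtree — those children must be born
  early for their descendants to fit) and then ascending rate, and improve
  by adjacent-transposition hill climbing with exact subtree scoring under
  a solve budget (`climb_budget`, default 25).

Ties (likelihood gap below 1e-9) always keep the earlier candidate, which
makes runs reproducible and leaves the node-index order in place when the
likelihood genuinely cannot distinguish permutations — e.g. leaf siblings
with equal rates.

EM iterations reuse the previous iteration's decision for any node whose
subtree rates are unchanged; the per-node decision depends only on the
subtree's shape and rates, so this reuse is exact, and it makes late EM
iterations (where most rates are clamped and static) nearly free.

## EM

`infer_rates()` alternates

* **M step** — orderings and times for the current rates
  (`best_orderings()`), and
* **E step** — `theta_i = d_i / (H - t_i)`, clamped into the box; leaves
  keep their previous value (they have no offspring to estimate from), and
  the root rate is fixed to the normal-tissue rate.

until the log-likelihood moves by less than `tol` (default 1e-6, maximum
100 iterations).  Because the rate update is a heuristic rather than the
likelihood's own stationary point in `theta` (which is
`(2 d_i + 1)/(H - t_i)`; available as `estep = "exact"`), monotonicity is
not guaranteed and the best iterate seen is returned.  Initialization is the
box midpoint by default, or seeded uniform draws (`init = "random"`).

## Restricted landscapes and model comparison

Under the `s`-model prior the landscape has at most `s` rate-change
vertices: a state is a set `X` of internal vertices plus one rate per
component of `T \ X`, the root component fixed at the normal rate.
`fit_s_model()` explores states by Metropolis search — 1-flip moves on `X`,
reflected Gaussian moves on rates — scoring each state by its profile
likelihood (maximized over times, horizon and orderings), and polishes the
best state's rates coordinate-wise.  For `s = 0` the single shared rate is
maximized directly in 1-D.  `compare_rate_models()` fits `s = 0` against
`s = 1` and reports the Bayes factor `exp(L2 - L1)` and the differences
`dAIC = 2(k1 - k2) + 2(L2 - L1)`, `dBIC = (k1 - k2) log(n) + 2(L2 - L1)`
with `k1 = 1`, `k2 = 3`.

## Rate uncertainty over tree posteriors

Point estimates inherit the uncertainty of the input tree.
`sample_trees()` runs a minimal Metropolis sampler over tree topologies
given the noisy genotype matrix — prune-and-reattach proposals (symmetric),
uniform tree prior, and the standard error model in which a true 1 drops
out with probability `alpha` and a true 0 appears with probability `beta`,
each cell attached to its best-matching clone profile.  It is a documented
stand-in for any external topology sampler: `rate_posterior()` equally
accepts a directory of tree files produced by other tools, which is the
primary interoperability path.  Rates are pooled across sampled trees *by
mutation label* (node indices are not comparable across topologies), over
internal nodes only, and summarized by mean, population spread `se`, and
relative spread.  Burn-in, thinning (default: every 10th state) and chain
length are configurable and recorded by the CLI.

## The simulator

`simulate_tumor()` generates ground truth as a continuous-time birth
process: the next event arrives after an exponential wait at the total rate
of all living clones; the parent is chosen proportionally to its rate; the
child receives an unused mutation label (uniform from `{1..m}`, without
replacement by default — `recurrent = TRUE` allows repeats) and a rate
drawn uniformly from the box (defaults `[0.005, 0.01]`).  The root rate is
drawn from the same box unless supplied.  The sampling time is the last
birth plus one further exponential wait, so the observation window contains
exactly the `m` recorded events — matching the event-count structure the
likelihood assumes.  Node ids follow birth order, hence the true sibling
orders are the index orders, and `add_noise()` produces the matched
single-cell genotype matrix (each clone replicated `copies` times, default
3, with dropout `alpha = 0.1` and false positives `beta = 1e-5` by
default).

What the simulator does *not* emulate: clone death, selection and fitness
differences, population sizes, doublets, and cell-level sampling biases.
Passing recovery tests on these simulations therefore demonstrates correct
inference under the model's own assumptions plus Poisson event timing — not
robustness to the full complexity of real tumor data.

## Accuracy metrics

`mapa()` is `1 - MAPE` (mean absolute percentage error); rate accuracy is
scored over internal non-root nodes (leaf rates are not estimable, the root
is fixed), time accuracy over all non-root event times.  `order_accuracy()`
is one minus the mean, over nodes with outdegree at least 2, of the Kendall
tau distance between true and inferred child orders normalized by the pair
count `d(d-1)/2` — the normalization puts the score on `[0, 1]`.

## Numerical choices

* Logs of non-positive gaps evaluate to `-Inf`/`NaN` penalties rather than
  errors, so optimizers see a well-defined surface.
* The star stationarity value `mu` is bracketed in
  `(H * sum(theta) + 1e-12, H * sum(theta) + d + 1)` — the defining sum
  decreases from infinity to below 1 there — solved by `uniroot` and
  polished by Newton steps to relative accuracy ~1e-12.
* Barrier continuation runs `mu = 1 ... 1e-9` with at most 60 Newton steps
  per stage; the active-set polish then solves the equality-constrained
  KKT system on the detected active set, drops constraints with
  negative multipliers, and snaps the solution onto the active manifold.
* The feasible-start slack is scaled from the narrowest constraint window
  and retried downward, so very tight band systems still start strictly
  inside.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state.

Problem sizes in the test-suite recovery benchmarks are 10 replicates at
`m = 70` with both initializations; property suites use trees of 3–20 nodes
with enumeration bounded by `prod(d_i!) <= 1e3` and brute-force budgets of
1e5 families.  These sizes were chosen as the smallest that exercise every
code path and give stable averages.

## Known limitations

* **Absolute time calibration.**  The Erlang-2 internal-branch density has
  mean gap `2/theta`, while Poisson-process data (including this package's
  own simulator) has mean gap `1/theta`.  Maximum-likelihood event times
  under the stated model therefore stretch systematically relative to such
  data even when the rates are known exactly, and the estimated sampling
  time `H` inherits a tree-dependent upward drift; in our experiments the
  aggregate exposure identity `sum(theta_i (H - t_i)) = n` holds exactly at
  free-`H` optima, but the scale within the tree redistributes.  *Relative*
  event times (scaled by `H`) are substantially more accurate than absolute
  ones.  Users comparing times across datasets should prefer the scaled
  times from `tidy(fit)$time / glance(fit)$horizon`.
* **Rate identifiability.**  An internal node's data about its rate is
  essentially its offspring count given its exposure — a Poisson
  observation with mean `theta * exposure`.  For typical outdegrees 1–3
  this carries limited information: with rates uniform on `[0.005, 0.01]`,
  the plug-in estimate `d/(H - t)` at the *true* times achieves MAPA near
  0.70, and no estimator of any kind can exceed about 0.84 (the Bayes bound
  computed from the posterior under the generative model).  Recovery
  numbers in that range are therefore expected, not a defect.
* **Order recovery.**  Where the likelihood genuinely distinguishes sibling
  permutations (different rates or subtree shapes), its argmax agrees with
  the true birth order only stochastically (~75–85% of pairs in our
  simulations); exact ties fall back to the stable input order.  Exhaustive
  enumeration confirms the search finds the likelihood's argmax — the
  remaining discordance is a property of the estimation problem, not the
  search.
* Wide polytomies (outdegree above `degree_cap`, default 9) require the
  heuristic tier (`control = list(heuristic = TRUE)`).
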