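# clonerate

Maximum-likelihood inference of **mutability landscapes** — per-subclone
mutation rates — for tumors profiled by single-cell sequencing.

Tumor cells are genomically unstable, and the instability itself varies
between subclones: mutation rates form a landscape over genotypes, the
mutation-rate analog of a fitness landscape.  Single-cell phylogeny tools
(SCITE, SiFit, SPhyR, PhISCS, ...) reconstruct a *mutation tree* whose
non-root nodes are mutation events and whose clones carry the mutations on
their root paths.  `clonerate` starts from such a tree and estimates, by
maximum likelihood, the quantities the tree leaves open:

* the mutation rate `θ_i` of every subclone (the landscape itself),
* the birth time `t_i` of every mutation event and the sampling time `H`,
* the birth order of siblings at every polytomy — equivalently the timed
  binary phylogeny `B(T)` consistent with the mutation tree.

The package is aimed at cancer genomicists who already have called mutation
trees or single-cell genotype matrices and want clone-level rate estimates,
rate-change tests, and calibrated uncertainty for them.

## Model in brief

For an ordering family `σ` (one birth order per node), the timed binary
phylogeny assigns clone `k`'s branches the densities
`θ_k² Δt e^{−θ_k Δt}` between consecutive birth events and
`θ_k e^{−θ_k (H − t)}` for the terminal branch to sampling.  The joint
log-likelihood is

    L(θ, t, H, σ) = Σ_i θ_i t_i + Σ_i Σ_j log(t_{σ_{i,j}} − t_{σ_{i,j−1}})
                    − H Σ_i θ_i + Σ_i (2 d_i + 1) log θ_i

and the estimate maximizes `L` jointly: EM alternates a convex event-time
solve plus a combinatorial ordering search (M step) with the rate update
`θ_i = d_i / (H − t_i)` clamped to a feasible box (E step).  Star trees
admit a closed-form stationary solution used both inside the optimizer and
as a test oracle.  A restricted "s-model" (at most `s` rate-change vertices)
is fitted by Metropolis search, and one-rate vs two-rate landscapes are
compared by Bayes factors and ΔAIC/ΔBIC.  Details, assumptions and known
limitations are in the methods vignette
(`vignettes/mutability-landscapes.Rmd`).

## Worked example

```r
library(clonerate)

tr <- read_mutation_tree("0 1 1 2 2 0 6 6", dialect = "parent_vector")
tr
#> <mutation_tree> 8 mutation nodes + root; max outdegree 2

fit <- infer_rates(tr, theta_min = 0.005, theta_max = 0.01, theta0 = 0.0075)
fit
#> <clonerate_fit> 8 mutations; logLik -92.8875; H 481.5; 11 EM iterations

tidy(fit)
#> # A tibble: 9 x 7
#>    node label parent outdegree   rate estimated  time
#>   <int> <chr>  <int>     <int>  <dbl> <lgl>     <dbl>
#> 1     0 <NA>      NA         2 0.0075 FALSE        0
#> 2     1 M1         0         2 0.006  TRUE       133.
#> 3     2 M2         1         2 0.01   TRUE       281.
#> 4     3 M3         1         0 0.0075 FALSE      481.
#> 5     4 M4         2         0 0.0075 FALSE      415.
#> 6     5 M5         2         0 0.0075 FALSE      481.
#> 7     6 M6         0         2 0.01   TRUE       281.
#> 8     7 M7         6         0 0.0075 FALSE      415.
#> 9     8 M8         6         0 0.0075 FALSE      481.
```

Each internal clone gets a rate (events per unit time, inside the
configured box; leaves have no offspring to estimate from and keep the
reference rate, flagged `estimated = FALSE`), a birth time in the same time
units, and the fit reports the sampling time `H` and attained
log-likelihood:

```r
glance(fit)
#> # A tibble: 1 x 5
#>   logLik horizon n_mutations iterations converged
#>    <dbl>   <dbl>       <int>      <int> <lgl>
#> 1  -92.9    481.           8         11 TRUE

autoplot(fit)                                   # timed phylogeny, rate-colored
as_newick(tr, fit$times, fit$horizon, fit$sigma) # export B(T) with branch lengths
```

Model comparison from maximum log-likelihoods (here with a Bayes factor of
5037 on a 20-mutation tree):

```r
model_compare(L1 = 0, L2 = log(5.037e3), n = 20)
#>     bf   log_bf delta_aic delta_bic    k1    k2     n
#> 1 5037     8.52      13.0      11.1     1     3    20
```

Simulation, benchmarking and uncertainty:

```r
truth <- simulate_tumor(m = 70, seed = 1)        # birth-process ground truth
bench <- benchmark_recovery(n_trees = 10, m = 70, seed = 1)
benchmark_summary(bench)                          # rate/time/order accuracy

gm    <- add_noise(truth, alpha = 0.1, beta = 1e-5, copies = 3, seed = 2)
trees <- sample_trees(gm, n_samples = 50, seed = 3)
rate_posterior(trees, 0.005, 0.01)                # per-mutation rate spread
```

A command-line front end with subcommands `infer`, `simulate`, `benchmark`,
`compare` and `posterior` ships as `inst/cli/clonerate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","clonerate.R",package="clonerate"))')" \
    infer --tree tree.txt --theta-min 0.005 --theta-max 0.01 --out out/
```

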