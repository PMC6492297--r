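# npcperm

Two-level permutation inference by non-parametric combination (NPC) of
replicated association tests.

## The problem

Some subject-level quantities are only available through many noisy
replications — for instance, a dynamic functional-connectivity summary
(a state-switching rate) recomputed from R independent re-runs of a
stochastic inference algorithm on each subject's fMRI. The question of
interest is whether the *underlying* quantity relates to observed
subject variables (behavior, demographics), not whether any single
replication does.

Testing each replication against the trait and averaging the R
p-values does not answer it: neither the arithmetic mean `p_mean`
(Edgington-style) nor the geometric mean

```
p_gmean = exp( (1/R) Σ_j log p_j )
```

(Fisher-style) distributes uniformly under the null, so neither is a
p-value, and both are dragged toward non-significance by the inevitable
noisy replications. `npcperm` implements the NPC remedy: keep the
combined summary as a *statistic* and calibrate it against its own
permutation null. With K synchronized permutations of the subject
labels,

```
p_NPC = ( #{k : p_gmean >= p_gmean^(k)} + 1 ) / (K + 1),
```

one valid p-value per observed variable, with min-p family-wise error
correction (`p_FWE`, from the per-permutation minimum summary across
variables) and Benjamini–Hochberg FDR across variables. A multivariate
comparator — ridge regression of the trait on all replications,
summarized by an F statistic inside the same permutation loop
(`p_regr`) — is included, together with the synthetic-data generators
and study runners (power and type-I-error grids) that characterize the
methods.

## Worked example

One reference variable over 100 subjects, 1,000 noisy replications of
it with coupling ceiling c = 0.1 (so most replications are barely
correlated with the trait), and a K = 10,000 NPC run:

```r
library(npcperm)
toy    <- gen_toy(N = 100, n_datasets = 1000, c = 0.1, seed = 1)
scheme <- make_permutation_scheme(N = 100, K = 10000, seed = 2)
res    <- npc_test(toy$B, toy$a, scheme)
res
#> NPC permutation test (gmean combining, K = 10000 permutations)
#>      p_mean p_gmean p_npc p_fwe p_fdr
#> var1 0.4596  0.3081 1e-04 1e-04 1e-04
```

The naive summaries (`p_mean` 0.46, `p_gmean` 0.31) sit nowhere near
significance — averaged p-values cannot see a weak effect spread across
replications. The calibrated NPC p-value is 1/10,001, the smallest
value K = 10,000 permutations can resolve: the observed geometric-mean
summary beat every permutation surrogate. With several traits, `p_fwe`
and `p_fdr` correct across them; here P = 1 and all three coincide.

Real data come in as delimited text (`read_matrix_file()`, one header
row, leading subject-ID column; optional exchangeability blocks via
`read_blocks()`), and results go out with `write_npc_results()`. The
same pipeline is scriptable from a shell:

```sh
Rscript inst/cli/npc.R test --replications Y.csv --traits X.csv \
    --nperm 10000 --seed 1 --out results.tsv
```

with `simulate` and `reproduce` subcommands for the synthetic studies
(`reproduce --study power --paper-scale` runs the full grid).

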