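---
title: "Two-level permutation inference for replicated noisy measurements"
author: "npcperm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level permutation inference for replicated noisy measurements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcperm)
```

## The problem

Some subject-level quantities can only be measured through many noisy
replications. The motivating case is dynamic functional connectivity: a
stochastic inference algorithm (for example, a hidden Markov model run on
resting-state fMRI) is re-run R times, and each run yields a slightly
different per-subject summary such as a state-switching rate. The
scientific question is whether the *underlying* quantity relates to
observed subject variables (behavior, demographics), not whether any one
replication does.

A tempting shortcut is to test each replication against the trait,
collect the R p-values, and average them. The arithmetic mean (an
Edgington-style summary, `p_mean`) and the geometric mean
(`p_gmean = exp(mean(log p))`, related to Fisher's combining statistic)
are both informative, but **neither is a p-value**: under the null
hypothesis they concentrate around 0.5 and `exp(-1)` respectively rather
than distributing uniformly. Reading them against a 0.05 threshold is
both invalid and, in practice, hopelessly conservative — a handful of
noisy replications with large p-values drags the average up even when
most replications carry signal.

## The model and procedure

`npc_test()` implements the non-parametric combination (NPC) remedy,
a two-level scheme:

1. **First level (parametric).** For every replication `y_j` (column of
   the N × R matrix Y) and trait `x_i` (column of the N × P matrix X),
   compute the two-sided p-value of the Pearson correlation via
   `t = r sqrt((N-2)/(1-r^2))` with N − 2 degrees of freedom. All of the
   package's analyses are correlation-based, so this is the default
   statistic-to-p mapping; any monotone alternative would serve, because
   validity comes from the second level.
2. **Combining.** Summarize each trait's R p-values with the geometric
   mean (default) or arithmetic mean. Log-space combining amplifies
   p-values near zero, which is what lets the test say "*at least some*
   replications carry a relationship" instead of "*all* do".
3. **Second level (permutation).** Permute the subject rows of X with K
   random permutations — the *same* permutations for every trait and
   replication, so dependence across traits is carried into the null —
   and recompute the combined summary each time. The NPC p-value is

   `p_NPC = (#{k : observed summary >= surrogate_k} + 1) / (K + 1)`,

   with ties counted conservatively and the `+1` accounting for the
   unpermuted arrangement (which is therefore *not* inserted among the K
   surrogates). The smallest attainable value is `1/(K+1)`, and every
   value is a multiple of it.
4. **Multiplicity.** Across traits, a min-p family-wise error corrected
   p-value uses the per-permutation minimum summary over traits
   (`fwe_correct()`), and Benjamini–Hochberg FDR (`fdr_bh()`, the
   independence/PRDS step-up form) adjusts the uncorrected NPC p-values.

Permuting rows of X is equivalent under the null to permuting rows of Y
and cheaper whenever P < R; it is the fixed implementation convention.

### Numerical choices

* First-level p-values are floored at `eps = 1e-300` (configurable)
  before logging, so a perfect correlation cannot produce `log(0)`. The
  floor only matters for the observed summary's *value*, not its rank,
  unless data are pathological.
* Correlations are computed as one matrix product of unit-normalized
  columns per permutation, so a K = 10,000 run over 1,000 replications
  takes seconds.
* Exchangeability blocks (e.g. family structure) restrict permutations
  to within-block shuffles. Whole-block swapping and deeper multi-level
  exchangeability are out of scope. If every block is a singleton the
  group degenerates to the identity and the scheme constructor refuses.
* Permutations are drawn uniformly *with replacement* from the
  (block-restricted) permutation group; with the intended K ≪ N! the
  chance of duplicates is negligible and enumeration is unnecessary.
* The identity permutation is excluded from the K surrogates by
  rejection; the estimator's `+1` already represents it.

## The ridge-regression baseline

`regression_perm_test()` is the multivariate comparator: regress each
trait on *all* replications at once, with a small ridge penalty
`lambda = lambda_rel * mean(diag(crossprod(Y)))` (default
`lambda_rel = 1e-3`) to keep the system well-posed when R ≥ N and to
temper overfitting. All coefficients are summarized by the standard
full-versus-intercept F statistic computed from the ridge fit's residual
sum of squares, referred parametrically to F(R, N − R − 1). The
reference distribution is knowingly approximate for a penalized fit;
that is immaterial because the parametric p-value is only a *ranking*
statistic inside the same synchronized permutation loop, which delivers
validity — any monotone transform of F would give the identical
permutation p-value. The degrees of freedom and the unquantified
"minimal penalty" were genuinely open choices; both are surfaced as
documented defaults rather than buried constants. Replications are
centered, not standardized: they are all on the same Fisher-z scale
already.

## What the generators emulate

`gen_toy()` builds the simplest replication family: one reference
variable `a ~ N(0,1)` over N = 100 subjects and 1,000 corrupted copies
`b = κ a + ε`, with `κ ~ U(0, c)` fresh per copy and ε standard normal.
The single `a` is shared by the whole family — the copies are
replications of one underlying relation, which is what the downstream
NPC run tests. `c ∈ {0, 0.1, 0.2}` spans no coupling to moderate
coupling. With `c = 0.2` the naive summaries hover well above any
significance level while the NPC p-value collapses to the permutation
floor; this is the package's canonical demonstration. One caveat worth
stating plainly: at `c = 0.2` the geometric-mean summary is centered
near 0.17 with a realization SD of about 0.03, so whether a single
realization lands above or below 0.2 is luck of the draw; at `c ≤ 0.1`
it sits stably near 0.3–0.38.

`gen_fc_dataset()` emulates the functional-connectivity study. Per
subject: a coupling `β_n ~ U(−0.2, 0.2)` (exactly 0 in the null regime),
a latent bivariate white-noise series of 10,000 samples with
`s2 = β s1 + ε` whose population channel correlation is
`c_n = β / sqrt(β² + 1)`, and an observed trait `x_n = c_n + 0.5 η_n`.
Each of the R replications subsamples T = 100 time points uniformly
without replacement — independently per replication, since replications
model independent noisy measurements — adds N(0, σ²) noise to both
channels, and records the Fisher-z of the channel correlation. The
latent noise ε has SD 1, which is what makes `c_n` exact. σ is the
difficulty dial; the study grid spans 0.25 to 1.5.

What these generators do **not** emulate: temporal autocorrelation
(the latent processes are white), real HMM inference, measurement
artifacts, non-Gaussian traits, or family structure in the trait. A
green simulation suite therefore shows calibration and power *under the
stated generative model*, not on real fMRI data.

`perturb_replications()` reproduces the situation where only some
replications carry signal: it subject-shuffles a random half (by
default) of the columns, destroying their association with every trait
while conserving each column's value multiset.

## Study runners and problem sizes

`run_toy_experiment()`, `run_power_grid()` and `run_null_grid()` wire
generators, scheme and tests together. A master seed deterministically
spawns per-cell seeds, and all methods inside one repetition share the
dataset and the permutation scheme, so method comparisons are paired.
The package's default study sizes are chosen to run on a desk machine:
the toy study at its full size (1,000 replications, K = 10,000, a few
seconds per coupling level), and the σ grids at 3 grid points × 20–50
repetitions with K = 500 (half a minute to a few minutes each), which
is enough to resolve the rejection-rate and ordering questions the
studies ask. The command-line `reproduce` runner defaults to a reduced
10-σ × 20-repetition grid and exposes `--paper-scale` for the full
30-σ × 100-repetition × K = 10,000 version, which takes hours.

Two behaviors the simulations establish (and the test suite re-checks):

* **Calibration.** Under the global null the NPC p-value is uniform on
  its attainable grid; across a 3-σ × 50-repetition null grid the
  rejection rate at α = 0.05 stays within binomial 99% bounds of 0.05,
  for both NPC and the ridge baseline.
* **Ordering.** With an effect present, mean p_NPC < mean p_gmean <
  mean p_mean at every σ, and NPC remains significant on average at the
  low-noise end where the naive summaries never approach 0.05.

## Known limitations

* First-level tests are parametric Pearson-correlation t-tests; rank
  statistics or nested first-level permutation are not provided (a
  different statistic-to-p mapping can be substituted upstream of the
  combining functions).
* No multivariate combining across traits (e.g. CCA-style) and no
  generalized-Pareto tail acceleration for extreme p-values: with
  K = 10,000 the resolution floor is 1/10,001.
* Within-block shuffling is the only exchangeability structure.
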