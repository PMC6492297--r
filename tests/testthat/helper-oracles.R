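# Independent oracles used across the suite.  These deliberately share no
# code with the package: brute-force loops, base-R reference routines.

# First-level p-value reference: base R's correlation test.
cor_p_oracle <- function(y, x) stats::cor.test(y, x)$p.value

# Monte-Carlo permutation p-value estimator, small summary = extreme.
perm_p_oracle <- function(obs, surrogates) {
  (sum(surrogates <= obs) + 1) / (length(surrogates) + 1)
}

# Step-up Benjamini-Hochberg, written as the textbook backward recursion.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

# Full two-level NPC by exhaustive looping over the supplied permutations:
# cor.test per replication/trait, geometric mean, counting estimators.
npc_oracle <- function(Y, X, perms, eps = 1e-300) {
  gmean <- function(p) exp(mean(log(pmax(p, eps))))
  P <- ncol(X)
  K <- nrow(perms)
  first <- function(Xmat, i) {
    apply(Y, 2, function(y) cor_p_oracle(y, Xmat[, i]))
  }
  obs <- vapply(seq_len(P), function(i) gmean(first(X, i)), numeric(1))
  null <- matrix(NA_real_, K, P)
  for (k in seq_len(K)) {
    Xk <- X[perms[k, ], , drop = FALSE]
    for (i in seq_len(P)) null[k, i] <- gmean(first(Xk, i))
  }
  p_npc <- vapply(seq_len(P),
                  function(i) perm_p_oracle(obs[i], null[, i]), numeric(1))
  min_k <- apply(null, 1, min)
  p_fwe <- vapply(seq_len(P),
                  function(i) (sum(min_k <= obs[i]) + 1) / (K + 1), numeric(1))
  list(obs = obs, null = null, p_npc = p_npc, p_fwe = p_fwe)
}

# Small random fixture shared by several tests.
make_fixture <- function(n = 12, R = 4, P = 2, seed = 101) {
  set.seed(seed)
  list(Y = matrix(rnorm(n * R), n, R), X = matrix(rnorm(n * P), n, P))
}
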