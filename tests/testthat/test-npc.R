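test_that("NPC matches an exhaustive brute-force enumeration on a tiny fixture", {
  fx <- make_fixture(n = 8, R = 3, P = 2, seed = 77)
  perms <- rbind(c(2, 1, 4, 3, 6, 5, 8, 7),
                 c(8, 7, 6, 5, 4, 3, 2, 1),
                 c(3, 1, 2, 5, 4, 8, 6, 7),
                 c(5, 6, 7, 8, 1, 2, 3, 4),
                 c(2, 3, 4, 5, 6, 7, 8, 1))
  sch <- permutation_scheme(perms)
  res <- npc_test(fx$Y, fx$X, sch, combiner = "gmean")
  ora <- npc_oracle(fx$Y, fx$X, perms)
  expect_equal(unname(res$observed), ora$obs, tolerance = 1e-12)
  expect_equal(res$null, ora$null, tolerance = 1e-12)
  expect_equal(unname(res$p_npc), ora$p_npc)
  expect_equal(unname(res$p_fwe), ora$p_fwe)
})

test_that("second-level counting follows the (count + 1) / (K + 1) estimator", {
  # K = 4 surrogates (0.2, 0.5, 0.01, 0.8), observed 0.1: one surrogate at
  # or below the observed summary -> (1 + 1) / 5.  With one variable the
  # min-p corrected value coincides with the uncorrected one.
  expect_equal(fwe_correct(0.1, matrix(c(0.2, 0.5, 0.01, 0.8))), 0.4)
  # observed at or above every surrogate -> p = 1
  expect_equal(fwe_correct(0.9, matrix(c(0.2, 0.5, 0.01, 0.8))), 1)
  # observed below every surrogate -> the attainable minimum
  expect_equal(fwe_correct(0.001, matrix(c(0.2, 0.5, 0.01, 0.8))), 1 / 5)
})

test_that("NPC p-values live on the attainable grid and corrections dominate", {
  fx <- make_fixture(n = 20, R = 5, P = 3, seed = 12)
  sch <- make_permutation_scheme(20, 37, seed = 8)
  res <- npc_test(fx$Y, fx$X, sch)
  grid <- (1:38) / 38
  expect_true(all(vapply(res$p_npc, function(p)
    any(abs(p - grid) < 1e-12), logical(1))))
  expect_true(all(res$p_npc >= 1 / 38 - 1e-15))
  expect_true(all(res$p_fwe >= res$p_npc - 1e-15))
  expect_true(all(res$p_fdr >= res$p_npc - 1e-15))
})

test_that("permutations are synchronized: reordering traits reorders results", {
  fx <- make_fixture(n = 16, R = 4, P = 3, seed = 3)
  colnames(fx$X) <- c("a", "b", "c")
  sch <- make_permutation_scheme(16, 60, seed = 21)
  res1 <- npc_test(fx$Y, fx$X, sch)
  res2 <- npc_test(fx$Y, fx$X[, c(3, 1, 2)], sch)
  expect_equal(res2$p_npc[c("a", "b", "c")], res1$p_npc[c("a", "b", "c")])
  expect_equal(res2$p_fwe[c("a", "b", "c")], res1$p_fwe[c("a", "b", "c")])
})

test_that("identical inputs and seed give identical results", {
  fx <- make_fixture(n = 14, R = 6, P = 2, seed = 44)
  sch <- make_permutation_scheme(14, 99, seed = 5)
  r1 <- npc_test(fx$Y, fx$X, sch)
  r2 <- npc_test(fx$Y, fx$X, make_permutation_scheme(14, 99, seed = 5))
  expect_identical(r1$p_npc, r2$p_npc)
  expect_identical(r1$null, r2$null)
})

test_that("mean combining is supported end to end", {
  fx <- make_fixture(n = 12, R = 4, P = 1, seed = 9)
  sch <- make_permutation_scheme(12, 49, seed = 2)
  res <- npc_test(fx$Y, fx$X, sch, combiner = "mean")
  expect_equal(unname(res$observed), unname(res$p_mean))
  # brute-force recount from the stored surrogate summaries
  expect_equal(unname(res$p_npc),
               perm_p_oracle(res$observed, res$null[, 1]))
})

test_that("NPC p-values are uniform on their grid under the global null", {
  # 200 independent null datasets; deciles of p_npc should be flat and the
  # rejection rate at alpha = 0.05 within binomial 99% bounds.
  n_sets <- 200; N <- 50; R <- 20; K <- 500
  seeds <- matrix(npcperm:::spawn_seeds(2024, 2 * n_sets), ncol = 2)
  p <- numeric(n_sets)
  for (s in seq_len(n_sets)) {
    set.seed(seeds[s, 1])
    Y <- matrix(rnorm(N * R), N, R)
    x <- rnorm(N)
    sch <- make_permutation_scheme(N, K, seed = seeds[s, 2])
    p[s] <- npc_test(Y, x, sch, keep_null = FALSE)$p_npc
  }
  counts <- table(cut(p, breaks = seq(0, 1, by = 0.1)))
  gof <- suppressWarnings(chisq.test(as.vector(counts)))
  expect_gt(gof$p.value, 0.01)
  rej <- mean(p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), n_sets, 0.05) / n_sets
  expect_gte(rej, bounds[1])
  expect_lte(rej, bounds[2])
})
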