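test_that("a trait orthogonal to all replications gives F ~ 0 and p ~ 1", {
  set.seed(21)
  Y <- matrix(rnorm(30 * 4), 30, 4)
  x0 <- rnorm(30)
  x <- resid(lm(x0 ~ Y))        # exactly orthogonal to centered Y columns
  fit <- ridge_f_pvalue(Y, x)
  expect_lt(abs(fit$f_stat), 1e-8)
  expect_gt(fit$p_parametric, 1 - 1e-6)
  expect_true(all(abs(fit$coef) < 1e-8))
})

test_that("with one replication and vanishing penalty, F converges to t^2", {
  set.seed(22)
  y <- rnorm(25)
  x <- 0.5 * y + rnorm(25)
  fit <- ridge_f_pvalue(matrix(y), x, lambda_rel = 1e-12)
  r <- cor(y, x)
  t2 <- r^2 * (25 - 2) / (1 - r^2)
  expect_equal(fit$f_stat, t2, tolerance = 1e-6)
  # and the shrunken F stays below the unpenalized t^2
  expect_lt(ridge_f_pvalue(matrix(y), x, lambda_rel = 0.5)$f_stat, t2)
})

test_that("F decreases monotonically as the penalty grows", {
  set.seed(23)
  Y <- matrix(rnorm(40 * 6), 40, 6)
  x <- Y %*% runif(6, -0.5, 0.5) + rnorm(40)
  fs <- vapply(10^seq(-6, 6, by = 2),
               function(l) ridge_f_pvalue(Y, x, lambda_rel = l)$f_stat,
               numeric(1))
  expect_true(all(diff(fs) < 0))
})

test_that("an unpenalized fit on a singular system is refused", {
  set.seed(24)
  Y <- matrix(rnorm(5 * 8), 5, 8)   # R > N: Gram matrix rank-deficient
  x <- rnorm(5)
  expect_error(ridge_f_pvalue(Y, x, lambda_rel = 0), "positive")
  expect_silent(ridge_f_pvalue(Y, x, lambda_rel = 1e-3))
})

test_that("the regression permutation test is deterministic and grid-valued", {
  set.seed(25)
  Y <- matrix(rnorm(30 * 5), 30, 5)
  X <- cbind(drop(Y %*% rep(0.4, 5)) + rnorm(30), rnorm(30))
  colnames(X) <- c("t1", "t2")
  sch <- make_permutation_scheme(30, 99, seed = 6)
  r1 <- regression_perm_test(Y, X, sch)
  r2 <- regression_perm_test(Y, X, sch)
  expect_identical(r1$p_regr, r2$p_regr)
  grid <- (1:100) / 100
  expect_true(all(vapply(r1$p_regr, function(p)
    any(abs(p - grid) < 1e-12), logical(1))))
  # strong signal for t1 -> observed beats every surrogate
  expect_equal(unname(r1$p_regr["t1"]), 1 / 100)
  expect_gt(unname(r1$p_regr["t2"]), 0.05)
})
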