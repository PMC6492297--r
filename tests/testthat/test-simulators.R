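test_that("toy generator: zero coupling ceiling means independent columns", {
  toy <- gen_toy(N = 100, n_datasets = 1000, c = 0, seed = 60)
  expect_true(all(toy$kappa == 0))
  rs <- cor(toy$a, toy$B)[1, ]
  # under independence E[r] = 0 with SD ~ 1/sqrt(N - 1) per column
  se_mean <- (1 / sqrt(99)) / sqrt(1000)
  expect_lt(abs(mean(rs)), 3 * se_mean)
})

test_that("toy generator: positive coupling ceiling shifts correlations up", {
  toy <- gen_toy(N = 100, n_datasets = 1000, c = 0.2, seed = 61)
  rs <- cor(toy$a, toy$B)[1, ]
  expect_gt(mean(rs), 3 * sd(rs) / sqrt(1000))
  expect_true(all(toy$kappa >= 0 & toy$kappa <= 0.2))
})

test_that("toy generator is a pure function of its seed", {
  t1 <- gen_toy(N = 20, n_datasets = 30, c = 0.1, seed = 7)
  t2 <- gen_toy(N = 20, n_datasets = 30, c = 0.1, seed = 7)
  expect_identical(t1$a, t2$a)
  expect_identical(t1$B, t2$B)
})

test_that("coupling-to-correlation map matches its closed form and simulation", {
  expect_equal(beta_to_corr(0), 0)
  expect_equal(beta_to_corr(1), 1 / sqrt(2))
  expect_equal(beta_to_corr(-1), -1 / sqrt(2))
  # Monte-Carlo: empirical corr of the generative pair within 3 SE
  set.seed(62)
  lat <- simulate_latent_pair(0.2, 10000)
  rho <- beta_to_corr(0.2)
  se <- (1 - rho^2) / sqrt(10000)
  expect_lt(abs(cor(lat$s1, lat$s2) - rho), 3 * se)
})

test_that("FC generator: null regime decouples trait and replications", {
  n_sets <- 60
  seeds <- npcperm:::spawn_seeds(63, n_sets)
  rs <- vapply(seeds, function(s) {
    d <- gen_fc_dataset(N = 30, R = 5, n_time = 50, sigma = 0.5,
                        latent_len = 500, effect = FALSE, seed = s)
    cor(d$x, rowMeans(d$Y))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(n_sets))
  expect_true(all(vapply(seeds[1:3], function(s)
    all(gen_fc_dataset(N = 10, R = 3, sigma = 0.5, latent_len = 200,
                       effect = FALSE, seed = s)$beta == 0), logical(1))))
})

test_that("FC generator: heavy measurement noise attenuates the association", {
  d_lo <- gen_fc_dataset(N = 100, R = 20, sigma = 0.25, latent_len = 2000,
                         seed = 64)
  d_hi <- gen_fc_dataset(N = 100, R = 20, sigma = 50, latent_len = 2000,
                         seed = 64)
  mean_abs_r <- function(d) mean(abs(cor(d$x, d$Y)[1, ]))
  expect_lt(mean_abs_r(d_hi), mean_abs_r(d_lo))
})

test_that("FC generator: stronger coupling raises the replication values", {
  d <- gen_fc_dataset(N = 200, R = 20, sigma = 0.25, latent_len = 2000,
                      seed = 65)
  hi <- rowMeans(d$Y)[d$beta > 0.15]
  lo <- rowMeans(d$Y)[d$beta < -0.15]
  expect_gt(mean(hi), mean(lo))
})

test_that("FC generator is seed-reproducible", {
  d1 <- gen_fc_dataset(N = 10, R = 4, sigma = 0.5, latent_len = 300, seed = 66)
  d2 <- gen_fc_dataset(N = 10, R = 4, sigma = 0.5, latent_len = 300, seed = 66)
  expect_identical(d1$Y, d2$Y)
  expect_identical(d1$x, d2$x)
})

test_that("perturbation shuffles within columns and only in the chosen fraction", {
  set.seed(67)
  Y <- matrix(rnorm(30 * 100), 30, 100)
  expect_identical(perturb_replications(Y, fraction = 0, seed = 1), Y)

  full <- perturb_replications(Y, fraction = 1, seed = 2)
  for (j in 1:100) {
    expect_equal(sort(full[, j]), sort(Y[, j]))
  }

  half <- perturb_replications(Y, fraction = 0.5, seed = 3)
  changed <- vapply(1:100, function(j) !all(half[, j] == Y[, j]), logical(1))
  expect_equal(sum(changed), 50)
  for (j in which(changed)) expect_equal(sort(half[, j]), sort(Y[, j]))
  expect_identical(half, perturb_replications(Y, fraction = 0.5, seed = 3))
})
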