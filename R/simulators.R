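# Synthetic-data generators: the toy coupled-pair study, the
# functional-connectivity (FC) replication simulation, and a column
# perturbation scheme that emulates replications unrelated to behavior.
# All generators are pure functions of their arguments (seed in, same
# data out) and never disturb the caller's RNG state.

#' Generate the toy coupled-pair datasets
#'
#' One reference variable `a ~ N(0, 1)` over `N` subjects is shared by a
#' family of `n_datasets` corrupted copies: column j of `B` is
#' `b = kappa_j * a + eps`, with `kappa_j ~ U(0, c)` drawn fresh per
#' dataset and `eps ~ N(0, 1)` fresh per entry.  `c` sets the expected
#' strength of the coupling: `c = 0` gives fully independent columns,
#' while even a modest `c` makes some columns (those with a lucky large
#' `kappa`) clearly correlated with `a`.
#'
#' @param N subjects (default 100).
#' @param n_datasets corrupted copies of `a` to generate (default 1000).
#' @param c maximum coupling coefficient, >= 0.
#' @param seed integer seed.
#' @return list with `a` (length N), `B` (N x n_datasets), `kappa`
#'   (length n_datasets), and the generating parameters.
#' @export
gen_toy <- function(N = 100, n_datasets = 1000, c = 0, seed = 1) {
  stopifnot(c >= 0, N >= 3, n_datasets >= 1)
  with_seed(seed, {
    a <- stats::rnorm(N)
    kappa <- stats::runif(n_datasets, 0, c)
    B <- outer(a, kappa) + matrix(stats::rnorm(N * n_datasets), N, n_datasets)
    list(a = a, B = B, kappa = kappa, N = N, n_datasets = n_datasets,
         c = c, seed = seed)
  })
}

#' Latent correlation implied by a coupling coefficient
#'
#' For the generative model `s2 = beta * s1 + eps` with `s1` and `eps`
#' independent standard Gaussians, the population correlation between
#' `s1` and `s2` is `beta / sqrt(beta^2 + 1)`.
#'
#' @param beta coupling coefficient(s), finite.
#' @return the implied correlation(s), in (-1, 1).
#' @export
beta_to_corr <- function(beta) {
  stopifnot(all(is.finite(beta)))
  beta / sqrt(beta^2 + 1)
}

#' Simulate one latent bivariate series
#'
#' The noiseless "neural process" underlying the FC simulation: `s1` is
#' standard Gaussian white noise of length `len`, and
#' `s2 = beta * s1 + eps` with `eps` standard Gaussian, so that
#' `cor(s1, s2)` converges to [beta_to_corr()] of `beta`.
#'
#' @param beta coupling coefficient.
#' @param len series length.
#' @return list with numeric vectors `s1` and `s2`.
#' @export
simulate_latent_pair <- function(beta, len) {
  s1 <- stats::rnorm(len)
  s2 <- beta * s1 + stats::rnorm(len)
  list(s1 = s1, s2 = s2)
}

#' Generate one functional-connectivity replication dataset
#'
#' Emulates relating a behavioral trait to a subject-level connectivity
#' coefficient that is only observable through repeated noisy
#' measurements.  Per subject n:
#'
#' * a coupling `beta_n ~ U(beta_lo, beta_hi)` (or exactly 0 when
#'   `effect = FALSE`, the global-null regime used for type-I-error
#'   calibration);
#' * a latent bivariate series of `latent_len` samples built by
#'   [simulate_latent_pair()]; its population channel correlation is
#'   `c_n = beta_n / sqrt(beta_n^2 + 1)`;
#' * the observed trait `x_n = c_n + 0.5 * eta_n`, `eta_n ~ N(0, 1)`;
#' * for each of `R` replications, `n_time` time points are subsampled
#'   uniformly without replacement (independently per replication),
#'   Gaussian measurement noise of standard deviation `sigma` is added to
#'   both channels, and the replication value is the Fisher
#'   z-transformed channel correlation.
#'
#' `sigma` is the difficulty dial: larger measurement noise attenuates
#' the channel correlation and with it the detectable association between
#' `Y` and `x`.
#'
#' @param N subjects (default 200).
#' @param R replications per subject (default 100).
#' @param n_time time points per noisy measurement (default 100).
#' @param sigma measurement-noise standard deviation (> 0).
#' @param beta_lo,beta_hi coupling range (defaults -0.2, 0.2).
#' @param latent_len latent series length (default 10000).
#' @param effect `FALSE` forces `beta_n = 0` for every subject.
#' @param seed integer seed.
#' @return list with `Y` (N x R Fisher-z replication matrix), `x`
#'   (length-N trait), `beta` (length-N couplings), and the parameters.
#' @export
gen_fc_dataset <- function(N = 200, R = 100, n_time = 100, sigma = 0.25,
                           beta_lo = -0.2, beta_hi = 0.2,
                           latent_len = 10000, effect = TRUE, seed = 1) {
  stopifnot(n_time >= 3, sigma > 0, beta_lo <= beta_hi, latent_len >= n_time)
  with_seed(seed, {
    beta <- if (effect) stats::runif(N, beta_lo, beta_hi) else rep(0, N)
    cn <- beta_to_corr(beta)
    x <- cn + 0.5 * stats::rnorm(N)
    Y <- matrix(NA_real_, N, R)
    for (n in seq_len(N)) {
      lat <- simulate_latent_pair(beta[n], latent_len)
      idx <- vapply(seq_len(R),
                    function(j) sample.int(latent_len, n_time),
                    integer(n_time))
      D1 <- matrix(lat$s1[idx], n_time, R) +
        matrix(stats::rnorm(n_time * R, 0, sigma), n_time, R)
      D2 <- matrix(lat$s2[idx], n_time, R) +
        matrix(stats::rnorm(n_time * R, 0, sigma), n_time, R)
      Y[n, ] <- fisher_z(col_cor(D1, D2))
    }
    list(Y = Y, x = x, beta = beta, N = N, R = R, n_time = n_time,
         sigma = sigma, effect = effect, seed = seed)
  })
}

# Correlation between matched columns of two matrices, vectorized.
col_cor <- function(A, B) {
  n <- nrow(A)
  ma <- colMeans(A); mb <- colMeans(B)
  ca <- colMeans(A * B) - ma * mb
  va <- colMeans(A * A) - ma^2
  vb <- colMeans(B * B) - mb^2
  ca / sqrt(va * vb)
}

#' Shuffle a fraction of replication columns across subjects
#'
#' Emulates the situation where only some replications carry signal: a
#' random `ceiling(fraction * R)`-subset of columns has its rows
#' independently subject-permuted (destroying any subject-level
#' association while conserving each column's value multiset); the other
#' columns are untouched.
#'
#' @param Y N x R replication matrix.
#' @param fraction share of columns to corrupt, in `[0, 1]` (default 0.5).
#' @param seed integer seed.
#' @return the perturbed matrix, same dimensions and dimnames as `Y`.
#' @export
perturb_replications <- function(Y, fraction = 0.5, seed = 1) {
  stopifnot(fraction >= 0, fraction <= 1)
  Y <- as.matrix(Y)
  n_corrupt <- ceiling(fraction * ncol(Y))
  if (n_corrupt == 0L) return(Y)
  with_seed(seed, {
    cols <- sample.int(ncol(Y), n_corrupt)
    for (j in cols) Y[, j] <- Y[sample.int(nrow(Y)), j]
    Y
  })
}
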