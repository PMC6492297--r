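# Experiment runners: the toy combining study, and power / type-I-error
# grids over the measurement-noise level sigma.  A single master seed
# deterministically spawns per-cell seeds, and all methods within a cell
# see the same dataset and the same permutation scheme.

#' Run the toy combining experiment for one coupling ceiling
#'
#' Generates a family of `n_datasets` corrupted copies of one reference
#' variable ([gen_toy()]), treats the copies as replications of a single
#' underlying relation, and runs the full NPC procedure: first-level
#' correlation p-values, mean and geometric-mean summaries, and the
#' second-level permutation p-value.
#'
#' @param N subjects (default 100).
#' @param n_datasets replicate datasets / replications (default 1000).
#' @param c maximum coupling, >= 0.
#' @param K permutations for the second level (default 10000, so the
#'   smallest attainable p is 1/10001).
#' @param seed master seed; data and scheme seeds are spawned from it.
#' @return list with scalars `p_mean`, `p_gmean`, `p_npc`, plus the
#'   underlying `npc_result` as `fit`.
#' @export
run_toy_experiment <- function(N = 100, n_datasets = 1000, c = 0,
                               K = 10000, seed = 1) {
  seeds <- spawn_seeds(seed, 2)
  toy <- gen_toy(N = N, n_datasets = n_datasets, c = c, seed = seeds[1])
  scheme <- make_permutation_scheme(N, K, seed = seeds[2])
  fit <- npc_test(toy$B, matrix(toy$a, ncol = 1), scheme,
                  combiner = "gmean", keep_null = FALSE)
  list(p_mean = unname(fit$p_mean), p_gmean = unname(fit$p_gmean),
       p_npc = unname(fit$p_npc), c = c, K = K, fit = fit)
}

#' Power / null grid over measurement-noise levels
#'
#' For every `sigma` in `sigma_values` and every repetition, generates one
#' functional-connectivity dataset ([gen_fc_dataset()]) and computes the
#' requested method p-values on it: `mean` and `gmean` (the observed
#' combining statistics), `npc` (the second-level NPC p-value) and `regr`
#' (the ridge-regression permutation p-value).  All methods within a
#' repetition share the dataset and the permutation scheme, so method
#' comparisons are paired.
#'
#' @param sigma_values strictly increasing noise levels.
#' @param repetitions realizations per sigma.
#' @param K permutations per test.
#' @param N,R,n_time,latent_len,beta_lo,beta_hi dataset parameters, see
#'   [gen_fc_dataset()].
#' @param methods subset of `c("mean", "gmean", "npc", "regr")`.
#' @param effect `FALSE` for the global-null (type-I-error) regime.
#' @param lambda_rel ridge penalty for the `regr` method.
#' @param seed master seed.
#' @return object of class `npc_experiment_report`: list with `raw`
#'   (data frame: sigma, rep, method, p), `summary` (per sigma x method:
#'   mean p, standard error, and the 95% band mean -/+ 2 SE), and
#'   `config`.
#' @export
run_power_grid <- function(sigma_values = c(0.25, 0.75, 1.5),
                           repetitions = 20, K = 500,
                           N = 200, R = 50, n_time = 100,
                           latent_len = 10000,
                           beta_lo = -0.2, beta_hi = 0.2,
                           methods = c("mean", "gmean", "npc", "regr"),
                           effect = TRUE, lambda_rel = 1e-3, seed = 1) {
  stopifnot(!is.unsorted(sigma_values, strictly = TRUE), repetitions >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  cells <- expand.grid(rep = seq_len(repetitions), sigma = sigma_values,
                       KEEP.OUT.ATTRS = FALSE)
  seeds <- matrix(spawn_seeds(seed, 2L * nrow(cells)), ncol = 2)
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sg <- cells$sigma[i]
    dat <- gen_fc_dataset(N = N, R = R, n_time = n_time, sigma = sg,
                          beta_lo = beta_lo, beta_hi = beta_hi,
                          latent_len = latent_len, effect = effect,
                          seed = seeds[i, 1])
    scheme <- make_permutation_scheme(N, K, seed = seeds[i, 2])
    p <- c()
    if (any(c("mean", "gmean", "npc") %in% methods)) {
      fit <- npc_test(dat$Y, matrix(dat$x, ncol = 1), scheme,
                      combiner = "gmean", keep_null = FALSE)
      if ("mean" %in% methods)  p["mean"]  <- unname(fit$p_mean)
      if ("gmean" %in% methods) p["gmean"] <- unname(fit$p_gmean)
      if ("npc" %in% methods)   p["npc"]   <- unname(fit$p_npc)
    }
    if ("regr" %in% methods) {
      rfit <- regression_perm_test(dat$Y, matrix(dat$x, ncol = 1), scheme,
                                   lambda_rel = lambda_rel)
      p["regr"] <- unname(rfit$p_regr)
    }
    rows[[i]] <- data.frame(sigma = sg, rep = cells$rep[i],
                            method = names(p), p = unname(p),
                            stringsAsFactors = FALSE)
  }
  raw <- do.call(rbind, rows)
  row.names(raw) <- NULL
  structure(list(raw = raw, summary = summarize_experiment(raw),
                 config = list(sigma_values = sigma_values,
                               repetitions = repetitions, K = K, N = N,
                               R = R, n_time = n_time,
                               latent_len = latent_len,
                               beta_lo = beta_lo, beta_hi = beta_hi,
                               methods = methods, effect = effect,
                               lambda_rel = lambda_rel, seed = seed)),
            class = "npc_experiment_report")
}

#' Type-I-error grid (global null)
#'
#' [run_power_grid()] with the coupling switched off (`beta_n = 0` for all
#' subjects), so any rejection is a false positive.
#'
#' @inheritParams run_power_grid
#' @export
run_null_grid <- function(sigma_values = c(0.25, 0.75, 1.5),
                          repetitions = 20, K = 500,
                          N = 200, R = 50, n_time = 100,
                          latent_len = 10000,
                          methods = c("mean", "gmean", "npc", "regr"),
                          lambda_rel = 1e-3, seed = 1) {
  run_power_grid(sigma_values = sigma_values, repetitions = repetitions,
                 K = K, N = N, R = R, n_time = n_time,
                 latent_len = latent_len, methods = methods,
                 effect = FALSE, lambda_rel = lambda_rel, seed = seed)
}

# Per-(sigma, method) mean, standard error and 95% band (mean -/+ 2 SE).
summarize_experiment <- function(raw) {
  agg <- do.call(rbind, lapply(split(raw, list(raw$sigma, raw$method), drop = TRUE),
    function(d) {
      m <- mean(d$p)
      se <- stats::sd(d$p) / sqrt(nrow(d))
      data.frame(sigma = d$sigma[1], method = d$method[1],
                 mean_p = m, se = se, lo = m - 2 * se, hi = m + 2 * se,
                 n = nrow(d), stringsAsFactors = FALSE)
    }))
  agg <- agg[order(agg$method, agg$sigma), ]
  row.names(agg) <- NULL
  agg
}

#' @export
print.npc_experiment_report <- function(x, digits = 4, ...) {
  cfg <- x$config
  cat(sprintf("Experiment grid: %d sigma value(s) x %d repetition(s), K = %d, %s\n",
              length(cfg$sigma_values), cfg$repetitions, cfg$K,
              if (cfg$effect) "with effect" else "global null"))
  s <- x$summary
  s[c("mean_p", "se", "lo", "hi")] <- round(s[c("mean_p", "se", "lo", "hi")], digits)
  print(s)
  invisible(x)
}
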