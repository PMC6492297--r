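#' First-level correlation tests between every replication and every trait
#'
#' Computes, for each replication column of `Y` and each trait column of
#' `X`, the two-sided parametric p-value for the Pearson correlation via
#' the t-transform `t = r * sqrt((N - 2) / (1 - r^2))` referred to the t
#' distribution with `N - 2` degrees of freedom.  These per-replication
#' p-values are the raw material that [npc_test()] combines; they are
#' parametric by design — all permutation happens at the second level.
#'
#' P-values are floored at `eps` so that subsequent log-space combining
#' ([combine_gmean()]) stays finite even for perfect correlations.
#'
#' @param Y numeric N x R matrix of replications (subjects in rows).
#' @param X numeric N x P matrix of observed variables, or a vector for a
#'   single trait.
#' @param eps floor applied to the p-values (default `1e-300`).
#' @return an object of class `npc_first_level`: a list with `p0` (R x P
#'   matrix of p-values), `r` (R x P Pearson correlations) and `df`
#'   (`N - 2`).
#' @export
#' @examples
#' set.seed(1)
#' Y <- matrix(rnorm(40), 10, 4)
#' x <- rnorm(10)
#' first_level_pvalues(Y, x)$p0
first_level_pvalues <- function(Y, X, eps = 1e-300) {
  Y <- check_matrix(Y, "Y")
  X <- check_matrix(X, "X")
  check_same_n(Y, X)
  df <- nrow(Y) - 2L
  r <- stats::cor(Y, X)
  p0 <- cor_to_p(r, df, eps)
  dimnames(p0) <- dimnames(r) <- list(col_labels(Y, "repl"), col_labels(X, "var"))
  structure(list(p0 = p0, r = r, df = df), class = "npc_first_level")
}

# Vectorized two-sided p for Pearson r with df = N - 2.  |r| numerically
# at or above 1 maps to t = Inf and hence to the eps floor.
cor_to_p <- function(r, df, eps) {
  one_minus_r2 <- pmax(1 - r * r, 0)
  tt <- abs(r) * sqrt(df / one_minus_r2)   # Inf where |r| >= 1
  p <- 2 * stats::pt(tt, df, lower.tail = FALSE)
  pmax(pmin(p, 1), eps)
}

#' @export
print.npc_first_level <- function(x, ...) {
  cat(sprintf("First-level correlation tests: %d replications x %d variables, df = %d\n",
              nrow(x$p0), ncol(x$p0), x$df))
  cat(sprintf("p-value range: [%.3g, %.3g]\n", min(x$p0), max(x$p0)))
  invisible(x)
}
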