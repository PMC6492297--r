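#' Ridge-regression F-test of a trait on all replications
#'
#' The multivariate alternative to p-value combining: regress the trait on
#' all R replications at once with a small ridge penalty (which removes
#' the algebraic indeterminacy when R >= N and tempers overfitting), and
#' summarize all coefficients with a single F statistic comparing the
#' ridge fit against the intercept-only model.  The parametric p-value
#' uses the unpenalized reference distribution F(R, N - R - 1); it is a
#' ranking statistic for the permutation wrapper
#' [regression_perm_test()], which is what delivers validity — any
#' monotone transform of F would give the same permutation p-value.
#'
#' The penalty is expressed relative to the scale of the data:
#' `lambda = lambda_rel * mean(diag(crossprod(Y_centered)))`.
#'
#' @param Y numeric N x R replication matrix.
#' @param x length-N trait vector.
#' @param lambda_rel relative ridge penalty (default `1e-3`, a minimal
#'   penalty; must be > 0 when R >= N).
#' @param include_intercept handle the intercept by centering `Y` and `x`
#'   (default `TRUE`); the intercept itself is not penalized.
#' @return list with `f_stat`, `p_parametric`, `df1`, `df2`, `lambda`,
#'   `coef`.
#' @export
ridge_f_pvalue <- function(Y, x, lambda_rel = 1e-3, include_intercept = TRUE) {
  Y <- check_matrix(Y, "Y")
  x <- as.numeric(x)
  if (length(x) != nrow(Y)) stop("x must have one value per subject", call. = FALSE)
  n <- nrow(Y); R <- ncol(Y)
  if (include_intercept) {
    Yc <- sweep(Y, 2, colMeans(Y), "-")
    xc <- x - mean(x)
  } else {
    Yc <- Y; xc <- x
  }
  G <- crossprod(Yc)
  lambda <- lambda_rel * mean(diag(G))
  A <- G + diag(lambda, R)
  b <- tryCatch(solve(A, crossprod(Yc, xc)),
                error = function(e) {
                  stop("replication Gram matrix is singular; supply a positive lambda_rel",
                       call. = FALSE)
                })
  fitted <- Yc %*% b
  rss1 <- sum((xc - fitted)^2)
  rss0 <- sum(xc^2)
  df1 <- R
  df2 <- max(n - R - 1L, 1L)
  f_stat <- ((rss0 - rss1) / df1) / (rss1 / df2)
  p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  list(f_stat = f_stat, p_parametric = p, df1 = df1, df2 = df2,
       lambda = lambda, coef = drop(b))
}

#' Permutation test built on the ridge F summary
#'
#' Embeds [ridge_f_pvalue()] in the same synchronized permutation loop as
#' [npc_test()]: for each trait, the parametric F-test p-value is
#' recomputed under every permutation of the subject rows, and the final
#' p-value is `(#{k: p_k <= p_obs} + 1) / (K + 1)`.
#'
#' @inheritParams npc_test
#' @param lambda_rel relative ridge penalty, see [ridge_f_pvalue()].
#' @return object of class `npc_regr_result`: list with `f_stat`,
#'   `p_parametric`, `p_regr` (all length-P), `K`, `lambda_rel`.
#' @export
regression_perm_test <- function(Y, X, scheme, lambda_rel = 1e-3) {
  Y <- check_matrix(Y, "Y")
  X <- check_matrix(X, "X")
  check_same_n(Y, X)
  stopifnot(inherits(scheme, "perm_scheme"))
  if (scheme$N != nrow(Y)) {
    stop(sprintf("scheme is over %d subjects but data have %d", scheme$N, nrow(Y)),
         call. = FALSE)
  }
  n <- nrow(Y); R <- ncol(Y); P <- ncol(X); K <- scheme$K
  vars <- col_labels(X, "var")

  Yc <- sweep(Y, 2, colMeans(Y), "-")
  G <- crossprod(Yc)
  lambda <- lambda_rel * mean(diag(G))
  A <- G + diag(lambda, R)
  # Precompute the coefficient map M (R x N): coefficients are M %*% x for
  # any (centered) trait, permuted or not, since the penalty depends only
  # on Y.
  M <- tryCatch(solve(A, t(Yc)),
                error = function(e) {
                  stop("replication Gram matrix is singular; supply a positive lambda_rel",
                       call. = FALSE)
                })
  df1 <- R
  df2 <- max(n - R - 1L, 1L)
  Xc <- sweep(X, 2, colMeans(X), "-")

  f_from_x <- function(xc) {
    b <- M %*% xc
    fitted <- Yc %*% b
    rss1 <- sum((xc - fitted)^2)
    rss0 <- sum(xc^2)
    ((rss0 - rss1) / df1) / (rss1 / df2)
  }

  f_obs <- apply(Xc, 2, f_from_x)
  p_obs <- stats::pf(f_obs, df1, df2, lower.tail = FALSE)
  # Centering commutes with row permutation, so permute the centered traits.
  count <- numeric(P)
  for (k in seq_len(K)) {
    Xk <- Xc[scheme$perms[k, ], , drop = FALSE]
    f_k <- apply(Xk, 2, f_from_x)
    p_k <- stats::pf(f_k, df1, df2, lower.tail = FALSE)
    count <- count + (p_k <= p_obs)
  }
  p_regr <- (count + 1) / (K + 1)
  names(f_obs) <- names(p_obs) <- names(p_regr) <- vars
  structure(list(f_stat = f_obs, p_parametric = p_obs, p_regr = p_regr,
                 K = K, lambda_rel = lambda_rel, lambda = lambda,
                 df1 = df1, df2 = df2),
            class = "npc_regr_result")
}

#' @export
print.npc_regr_result <- function(x, digits = 4, ...) {
  cat(sprintf("Ridge-regression permutation test (lambda_rel = %g, K = %d)\n",
              x$lambda_rel, x$K))
  print(round(data.frame(f_stat = x$f_stat, p_parametric = x$p_parametric,
                         p_regr = x$p_regr), digits))
  invisible(x)
}
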