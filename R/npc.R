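#' Two-level non-parametric combination (NPC) permutation test
#'
#' Tests, for each observed variable (column of `X`), whether it is
#' associated with the unobserved quantity that the replication columns of
#' `Y` measure noisily.  The procedure is:
#'
#' 1. **First level** — parametric two-sided correlation p-values between
#'    every replication and every trait ([first_level_pvalues()]),
#'    summarized per trait by the geometric mean (or arithmetic mean).
#' 2. **Second level** — the rows of `X` are permuted `K` times with one
#'    shared scheme (synchrony across traits and replications); each
#'    permutation yields a surrogate summary.  The NPC p-value is the
#'    proportion of surrogates at least as extreme as the observed
#'    summary, with the `(count + 1) / (K + 1)` correction, so the
#'    smallest attainable value is `1 / (K + 1)`.
#' 3. **Multiplicity** — a min-p family-wise error corrected p-value per
#'    trait (distribution of the per-permutation minimum summary over
#'    traits, see [fwe_correct()]) and Benjamini-Hochberg FDR on the
#'    uncorrected NPC p-values.
#'
#' Permuting the rows of `X` is equivalent under the null to permuting the
#' rows of `Y` and is cheaper when there are fewer traits than
#' replications; it is the implemented convention.
#'
#' @param Y numeric N x R replication matrix.
#' @param X numeric N x P trait matrix (or length-N vector).
#' @param scheme a `perm_scheme` over the same N subjects, from
#'   [make_permutation_scheme()].
#' @param combiner `"gmean"` (default; log-space combining, sensitive to
#'   small p-values) or `"mean"` (Edgington-style).
#' @param eps floor for first-level p-values before log combining.
#' @param keep_null keep the K x P matrix of surrogate summaries in the
#'   result (needed for audit; default `TRUE`).
#' @return an object of class `npc_result`: list with `p_mean`, `p_gmean`
#'   (observed combining statistics, per trait), `p_npc` (second-level
#'   p-values), `p_fwe`, `p_fdr`, `observed` (the summary actually
#'   calibrated, per `combiner`), `null` (K x P surrogate summaries, or
#'   `NULL`), `first_level`, `combiner`, `K`.
#' @references The two-level combining scheme follows the non-parametric
#'   combination methodology of Pesarin & Salmaso and its neuroimaging
#'   formulation by Winkler and colleagues.
#' @export
#' @examples
#' set.seed(7)
#' Y <- matrix(rnorm(50 * 8), 50, 8)
#' x <- rnorm(50)
#' sch <- make_permutation_scheme(50, K = 199, seed = 11)
#' npc_test(Y, x, sch)
npc_test <- function(Y, X, scheme, combiner = c("gmean", "mean"),
                     eps = 1e-300, keep_null = TRUE) {
  combiner <- match.arg(combiner)
  Y <- check_matrix(Y, "Y")
  X <- check_matrix(X, "X")
  check_same_n(Y, X)
  stopifnot(inherits(scheme, "perm_scheme"))
  if (scheme$N != nrow(Y)) {
    stop(sprintf("scheme is over %d subjects but data have %d", scheme$N, nrow(Y)),
         call. = FALSE)
  }
  n <- nrow(Y)
  P <- ncol(X)
  K <- scheme$K
  df <- n - 2L
  vars <- col_labels(X, "var")

  fl <- first_level_pvalues(Y, X, eps = eps)
  obs_mean  <- combine_cols(fl$p0, "mean")
  obs_gmean <- combine_cols(fl$p0, "gmean")
  observed <- if (combiner == "gmean") obs_gmean else obs_mean

  # Unit-norm columns make crossprod() the exact correlation matrix, so the
  # permutation loop is one small matrix product per permutation.
  ys <- unit_scale(Y)
  xs <- unit_scale(X)
  null_summ <- matrix(NA_real_, nrow = K, ncol = P)
  for (k in seq_len(K)) {
    rk <- crossprod(ys, xs[scheme$perms[k, ], , drop = FALSE])
    pk <- cor_to_p(rk, df, eps)
    null_summ[k, ] <- combine_cols(pk, combiner)
  }

  p_npc <- (colSums(null_summ <= rep(observed, each = K)) + 1) / (K + 1)
  p_fwe <- fwe_correct(observed, null_summ)
  p_fdr <- fdr_bh(p_npc)

  names(p_npc) <- names(p_fwe) <- names(p_fdr) <- vars
  names(obs_mean) <- names(obs_gmean) <- names(observed) <- vars

  structure(list(p_mean = obs_mean, p_gmean = obs_gmean,
                 observed = observed, p_npc = p_npc,
                 p_fwe = p_fwe, p_fdr = p_fdr,
                 null = if (keep_null) null_summ else NULL,
                 first_level = fl, combiner = combiner, K = K),
            class = "npc_result")
}

#' Min-p family-wise error correction over traits
#'
#' For each trait `j`, counts the permutations whose minimum surrogate
#' summary across all traits is at least as extreme as (i.e. less than or
#' equal to) the observed summary of trait `j`, and applies the
#' `(count + 1) / (K + 1)` estimator.  Because the per-permutation minimum
#' over traits is never larger than any single trait's surrogate, the
#' corrected value dominates the uncorrected one elementwise.
#'
#' @param observed length-P vector of observed combined summaries.
#' @param null_summaries K x P matrix of surrogate summaries from the same
#'   synchronized permutations.
#' @return length-P vector of FWE-corrected p-values.
#' @export
fwe_correct <- function(observed, null_summaries) {
  null_summaries <- as.matrix(null_summaries)
  if (ncol(null_summaries) != length(observed)) {
    stop("null_summaries must have one column per observed summary", call. = FALSE)
  }
  K <- nrow(null_summaries)
  min_k <- do.call(pmin, lapply(seq_len(ncol(null_summaries)),
                                function(j) null_summaries[, j]))
  vapply(observed, function(o) (sum(min_k <= o) + 1) / (K + 1), numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (the independence / PRDS
#' form), as applied to the uncorrected NPC p-values across traits.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values, capped at 1.
#' @export
fdr_bh <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' @export
print.npc_result <- function(x, digits = 4, ...) {
  cat(sprintf("NPC permutation test (%s combining, K = %d permutations)\n",
              x$combiner, x$K))
  tab <- data.frame(p_mean = x$p_mean, p_gmean = x$p_gmean,
                    p_npc = x$p_npc, p_fwe = x$p_fwe, p_fdr = x$p_fdr)
  print(round(tab, digits))
  invisible(x)
}

#' Tidy one- or several-trait NPC results into a data frame
#'
#' @param x an `npc_result`.
#' @return data frame with one row per trait and columns `variable_id`,
#'   `p_mean`, `p_gmean`, `p_npc`, `p_fwe`, `p_fdr`.
#' @export
as.data.frame.npc_result <- function(x, ...) {
  data.frame(variable_id = names(x$p_npc),
             p_mean = unname(x$p_mean), p_gmean = unname(x$p_gmean),
             p_npc = unname(x$p_npc), p_fwe = unname(x$p_fwe),
             p_fdr = unname(x$p_fdr),
             stringsAsFactors = FALSE, row.names = NULL)
}
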