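#' Combine p-values by their arithmetic mean
#'
#' The Edgington-style summary of a vector of first-level p-values.  Note
#' that the result is a combining statistic, not itself a p-value: under
#' the global null it concentrates around 0.5 rather than distributing
#' uniformly.  A second-level permutation step (see [npc_test()]) is needed
#' to calibrate it.
#'
#' @param p numeric vector of p-values, all in (0, 1].
#' @return the arithmetic mean, a scalar in (0, 1].
#' @seealso [combine_gmean()] for the geometric-mean summary.
#' @export
#' @examples
#' combine_mean(c(0.2, 0.4))  # 0.3
combine_mean <- function(p) {
  check_pvec(p, positive_only = FALSE)
  mean(p)
}

#' Combine p-values by their geometric mean
#'
#' Exponentiates the average log p-value, `exp(mean(log(p)))`.  Working in
#' log space amplifies the influence of p-values near zero (the same
#' mechanism that powers Fisher's combining method) and avoids numerical
#' underflow for very small inputs.  Like [combine_mean()], the result is a
#' combining statistic that requires permutation calibration before it can
#' be read as a p-value.
#'
#' Entries must be strictly positive; callers holding exact zeros (e.g. a
#' correlation of 1 mapped to p = 0) are expected to floor them first, as
#' [first_level_pvalues()] does with its `eps` argument.
#'
#' @inheritParams combine_mean
#' @return the geometric mean, a scalar in (0, 1].
#' @export
#' @examples
#' combine_gmean(c(0.1, 0.001))  # 0.01
combine_gmean <- function(p) {
  check_pvec(p, positive_only = TRUE)
  exp(mean(log(p)))
}

check_pvec <- function(p, positive_only) {
  if (length(p) == 0L) stop("cannot combine an empty p-value vector", call. = FALSE)
  if (!is.numeric(p) || anyNA(p)) stop("p-values must be numeric and complete", call. = FALSE)
  if (any(p > 1)) stop("p-values must not exceed 1", call. = FALSE)
  if (positive_only && any(p <= 0)) {
    stop("p-values must be strictly positive; floor tiny values before combining",
         call. = FALSE)
  }
  if (!positive_only && any(p < 0)) stop("p-values must be nonnegative", call. = FALSE)
  invisible(p)
}

# Column-wise combiners used inside the permutation loop (no per-call
# validation; the caller guarantees floored inputs).
combine_cols <- function(pmat, combiner) {
  switch(combiner,
    gmean = exp(colMeans(log(pmat))),
    mean  = colMeans(pmat),
    stop("unknown combiner: ", combiner, call. = FALSE)
  )
}

#' Fisher z-transformation of a correlation coefficient
#'
#' The variance-stabilizing transform `atanh(r) = 0.5 * log((1 + r) / (1 - r))`,
#' which makes sample correlations approximately Gaussian and therefore
#' suitable for parametric testing.
#'
#' @param r correlation value(s), each strictly inside (-1, 1).
#' @return the transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    stop("fisher_z requires |r| < 1; the transform diverges at the boundary",
         call. = FALSE)
  }
  atanh(r)
}
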