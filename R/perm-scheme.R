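#' Build a synchronized permutation scheme
#'
#' Draws `K` random permutations of the subject indices `1..N`, uniformly
#' (with replacement from the permutation group), optionally restricted to
#' shuffle only within exchangeability blocks — e.g. families, within
#' which subjects are exchangeable but across which they are not.  The
#' same scheme is reused for every trait and every replication in
#' [npc_test()] and [regression_perm_test()], which is what makes the
#' resulting tests account for dependence across traits ("synchronized"
#' permutations).
#'
#' The identity permutation is never among the K surrogates: the observed
#' arrangement is accounted for by the `+1` of the permutation p-value
#' estimator `(count + 1) / (K + 1)`.
#'
#' @param N number of subjects (>= 2).
#' @param K number of permutations to draw (>= 1).
#' @param seed integer seed; the scheme is a pure function of its
#'   arguments.
#' @param blocks optional length-N vector of block labels; permutations
#'   then map each subject to a subject with the same label.
#' @return an object of class `perm_scheme`: list with `K`, `perms`
#'   (K x N integer matrix, each row a bijection of `1..N`), `blocks`,
#'   `seed`, `N`.
#' @export
#' @examples
#' sch <- make_permutation_scheme(6, 10, seed = 42, blocks = c(1, 1, 1, 2, 2, 2))
#' sch$perms[1, ]
make_permutation_scheme <- function(N, K, seed, blocks = NULL) {
  if (N < 2) stop("need at least 2 subjects to permute", call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (!is.null(blocks)) {
    if (length(blocks) != N) stop("blocks must have one label per subject", call. = FALSE)
    if (all(table(blocks) == 1L)) {
      stop("every block is a singleton: only the identity permutation exists",
           call. = FALSE)
    }
    block_idx <- split(seq_len(N), blocks)
  }
  identity_perm <- seq_len(N)
  perms <- with_seed(seed, {
    out <- matrix(0L, nrow = K, ncol = N)
    for (k in seq_len(K)) {
      repeat {
        if (is.null(blocks)) {
          perm <- sample.int(N)
        } else {
          perm <- identity_perm
          for (idx in block_idx) {
            if (length(idx) > 1L) perm[idx] <- idx[sample.int(length(idx))]
          }
        }
        if (!identical(perm, identity_perm)) break
      }
      out[k, ] <- perm
    }
    out
  })
  structure(list(K = K, perms = perms, blocks = blocks, seed = seed, N = N),
            class = "perm_scheme")
}

#' Construct a permutation scheme from explicit permutations
#'
#' For audit and testing: wrap a hand-built set of permutations in the
#' container [npc_test()] expects.  Each row must be a bijection of
#' `1..N`; block closure is verified when `blocks` is supplied.
#'
#' @param perms K x N integer matrix, one permutation per row.
#' @param blocks optional block labels, checked for closure.
#' @return a `perm_scheme` object.
#' @export
permutation_scheme <- function(perms, blocks = NULL) {
  perms <- as.matrix(perms)
  storage.mode(perms) <- "integer"
  N <- ncol(perms)
  for (k in seq_len(nrow(perms))) {
    if (!identical(sort(perms[k, ]), seq_len(N))) {
      stop(sprintf("row %d is not a bijection of 1..%d", k, N), call. = FALSE)
    }
    if (!is.null(blocks) && !all(blocks[perms[k, ]] == blocks)) {
      stop(sprintf("row %d moves a subject across blocks", k), call. = FALSE)
    }
  }
  structure(list(K = nrow(perms), perms = perms, blocks = blocks,
                 seed = NA_integer_, N = N),
            class = "perm_scheme")
}

#' @export
print.perm_scheme <- function(x, ...) {
  cat(sprintf("Permutation scheme: K = %d permutations of N = %d subjects%s\n",
              x$K, x$N,
              if (is.null(x$blocks)) "" else
                sprintf(" (%d exchangeability blocks)", length(unique(x$blocks)))))
  invisible(x)
}
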