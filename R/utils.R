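# Internal helpers: seeded evaluation and input validation.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state
# afterwards so that library calls never disturb user-level randomness.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  expr
}

# Deterministically derive `n` child seeds from one master seed.  Children
# stay below .Machine$integer.max so they are valid set.seed() inputs.
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147483646L, n))
}

# Coerce to a numeric matrix and enforce the shared invariants of the
# replication / trait containers: numeric, complete, N >= 3, and every
# column with nonzero variance (a constant column makes the correlation
# t-test degenerate).
check_matrix <- function(m, what, min_rows = 3L) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (is.vector(m) && is.numeric(m)) m <- matrix(m, ncol = 1L)
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  }
  if (anyNA(m)) stop(sprintf("'%s' contains missing values", what), call. = FALSE)
  if (nrow(m) < min_rows) {
    stop(sprintf("'%s' needs at least %d rows (subjects)", what, min_rows),
         call. = FALSE)
  }
  cn <- colnames(m)
  rng <- matrixStats_colRange(m)
  bad <- which(rng[1, ] == rng[2, ])
  if (length(bad)) {
    lab <- if (is.null(cn)) as.character(bad[1]) else cn[bad[1]]
    stop(sprintf("column '%s' of '%s' is constant (zero variance)", lab, what),
         call. = FALSE)
  }
  m
}

# Column ranges without extra dependencies.
matrixStats_colRange <- function(m) {
  rbind(apply(m, 2, min), apply(m, 2, max))
}

check_same_n <- function(Y, X) {
  if (nrow(Y) != nrow(X)) {
    stop(sprintf("dimension mismatch: Y has %d subjects but X has %d",
                 nrow(Y), nrow(X)), call. = FALSE)
  }
}

# Center columns and scale each to unit Euclidean norm, so that
# crossprod(ys, xs) is exactly the matrix of Pearson correlations.
unit_scale <- function(m) {
  m <- sweep(m, 2, colMeans(m), "-")
  nrm <- sqrt(colSums(m * m))
  sweep(m, 2, nrm, "/")
}

col_labels <- function(m, prefix) {
  if (!is.null(colnames(m))) colnames(m) else paste0(prefix, seq_len(ncol(m)))
}
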