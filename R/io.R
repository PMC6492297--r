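# Delimited-text I/O.  Matrices travel as CSV/TSV with one header row and
# a leading subject-ID column; results as TSV at full double precision.

#' Read a subjects-by-columns numeric matrix from CSV/TSV
#'
#' Expects one header row (replication or trait names) and a leading
#' subject-ID column, which becomes the rownames.  The separator is taken
#' from the file extension (`.tsv`/`.txt` tab, otherwise comma) unless
#' given explicitly.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) infers from the extension.
#' @return numeric matrix with subject IDs as rownames.
#' @export
read_matrix_file <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- sep %||% infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected a subject-ID column plus at least one data column",
                         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric values in ", path, call. = FALSE)
  rownames(m) <- as.character(df[[1]])
  m
}

#' Read exchangeability-block labels
#'
#' Two-column CSV/TSV: subject ID, block label.  Returned in the order of
#' `subject_ids` when supplied, so labels align with the matrix rows.
#'
#' @param path file path.
#' @param subject_ids optional character vector giving the row order of
#'   the data matrices.
#' @return vector of block labels.
#' @export
read_blocks <- function(path, subject_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("blocks file needs columns: subject_id, block_label",
                         call. = FALSE)
  labels <- df[[2]]
  names(labels) <- as.character(df[[1]])
  if (!is.null(subject_ids)) {
    miss <- setdiff(subject_ids, names(labels))
    if (length(miss)) stop("no block label for subject(s): ",
                           paste(utils::head(miss, 5), collapse = ", "),
                           call. = FALSE)
    labels <- labels[subject_ids]
  }
  labels
}

#' Write NPC (or regression) results as TSV
#'
#' One row per trait, p-value columns at full double precision
#' (`%.17g`), so the file round-trips exactly.
#'
#' @param result an `npc_result`, `npc_regr_result`, or data frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_npc_results <- function(result, path) {
  df <- if (inherits(result, "npc_result")) {
    as.data.frame(result)
  } else if (inherits(result, "npc_regr_result")) {
    data.frame(variable_id = names(result$p_regr),
               f_stat = unname(result$f_stat),
               p_parametric = unname(result$p_parametric),
               p_regr = unname(result$p_regr),
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(result)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Write a matrix in the package's input format (ID column + header).
write_matrix_file <- function(m, path, id_prefix = "subj") {
  ids <- rownames(m) %||% paste0(id_prefix, seq_len(nrow(m)))
  df <- data.frame(subject_id = ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

infer_sep <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a
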