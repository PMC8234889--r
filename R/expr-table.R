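#' Expression tables
#'
#' Throughout the package an expression matrix travels as a *wide tibble*:
#' a `gene_id` character column followed by one numeric column per sample.
#' Values are non-negative on the measurement scale (FPKM-UQ-like for genes,
#' RPM-like for miRNA) unless a function explicitly log-transforms them.
#'
#' `as_expr_tbl()` converts a genes-by-samples numeric matrix (rownames =
#' gene IDs) into this shape; `expr_matrix()` goes the other way.
#'
#' @param m A numeric matrix, genes in rows, samples in columns, with
#'   row and column names.
#' @param expr A wide expression tibble.
#' @return `as_expr_tbl()` a tibble; `expr_matrix()` a named numeric matrix.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expr_matrix(as_expr_tbl(m))
#' @export
as_expr_tbl <- function(m) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  tibble::as_tibble(m, rownames = "gene_id")
}

#' @rdname as_expr_tbl
#' @export
expr_matrix <- function(expr) {
  validate_expr(expr)
  m <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- expr$gene_id
  m
}

validate_expr <- function(expr) {
  if (!is.data.frame(expr) || ncol(expr) < 2 ||
      !is.character(expr[[1]]) && !is.factor(expr[[1]])) {
    stop("expression table must be a data frame with a gene_id column ",
         "followed by sample columns", call. = FALSE)
  }
  if (names(expr)[1] != "gene_id") {
    stop("first column of an expression table must be named 'gene_id'",
         call. = FALSE)
  }
  if (anyDuplicated(expr$gene_id)) {
    stop("duplicate gene IDs in expression table", call. = FALSE)
  }
  if (anyDuplicated(names(expr)[-1])) {
    stop("duplicate sample IDs in expression table", call. = FALSE)
  }
  invisible(expr)
}

sample_ids <- function(expr) names(expr)[-1]

#' Read / write tab-separated expression tables
#'
#' The on-disk format is plain TSV: header row of sample IDs, first column
#' `gene_id`. Clinical tables and other per-sample tables use ordinary
#' [readr::read_tsv()] conventions.
#'
#' @param path File path.
#' @param expr Wide expression tibble.
#' @return `read_expr_tsv()` returns a wide expression tibble;
#'   `write_expr_tsv()` returns `path` invisibly.
#' @export
read_expr_tsv <- function(path) {
  expr <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(expr)[1] <- "gene_id"
  validate_expr(expr)
  expr
}

#' @rdname read_expr_tsv
#' @export
write_expr_tsv <- function(expr, path) {
  validate_expr(expr)
  readr::write_tsv(expr, path, progress = FALSE)
  invisible(path)
}
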