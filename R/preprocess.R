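#' Keep protein-coding genes
#'
#' Restricts an expression table to genes annotated as `protein_coding` in
#' a biotype table. Genes missing from the annotation are dropped with a
#' warning.
#'
#' @param expr Wide expression tibble.
#' @param biotypes Data frame with columns `gene_id`, `biotype`.
#' @return Filtered expression tibble (same samples).
#' @export
filter_protein_coding <- function(expr, biotypes) {
  validate_expr(expr)
  stopifnot(all(c("gene_id", "biotype") %in% names(biotypes)))
  if (anyDuplicated(biotypes$gene_id)) {
    stop("duplicate gene IDs in biotype table", call. = FALSE)
  }
  missing <- setdiff(expr$gene_id, biotypes$gene_id)
  if (length(missing) > 0) {
    warning(length(missing), " gene(s) absent from biotype table dropped: ",
            paste(utils::head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ..." else "", call. = FALSE)
  }
  coding <- biotypes$gene_id[biotypes$biotype == "protein_coding"]
  out <- dplyr::filter(expr, .data$gene_id %in% coding)
  if (nrow(out) == 0) {
    stop("no protein-coding genes remain (started with ", nrow(expr), ")",
         call. = FALSE)
  }
  message("protein-coding filter: ", nrow(out), " of ", nrow(expr),
          " genes retained")
  out
}

#' Remove lowly expressed genes
#'
#' With more than 30 samples, keeps genes with nonzero expression in more
#' than 30 samples. With 30 samples or fewer, keeps genes whose zero
#' fraction is at most 30% (the sample-count rule is unsatisfiable there).
#'
#' @param expr Wide expression tibble.
#' @return Filtered expression tibble.
#' @export
filter_low_expression <- function(expr) {
  validate_expr(expr)
  m <- expr_matrix(expr)
  n <- ncol(m)
  nonzero <- rowSums(m != 0)
  keep <- if (n > 30) nonzero > 30 else (n - nonzero) / n <= 0.30
  message("low-expression filter (", if (n > 30) ">30 nonzero samples"
          else "<=30% zeros", "): ", sum(keep), " of ", nrow(m),
          " genes retained")
  expr[keep, , drop = FALSE]
}

#' Quantile-normalize an expression table
#'
#' Forces every sample (column) onto the common reference distribution given
#' by the row means of the column-sorted matrix. Ties within a column
#' receive the mean of the reference values at their rank positions
#' (average ranks with linear interpolation).
#'
#' @param expr Wide expression tibble with at least two samples.
#' @return Normalized expression tibble.
#' @examples
#' expr <- as_expr_tbl(matrix(c(5, 1, 2, 4), 2,
#'   dimnames = list(c("m1", "m2"), c("s1", "s2"))))
#' quantile_normalize(expr)
#' @export
quantile_normalize <- function(expr) {
  validate_expr(expr)
  m <- expr_matrix(expr)
  if (ncol(m) < 2) stop("quantile normalization needs >= 2 samples",
                        call. = FALSE)
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(x) {
    stats::approx(seq_along(ref), ref,
                  xout = rank(x, ties.method = "average"))$y
  })
  dimnames(out) <- dimnames(m)
  as_expr_tbl(out)
}

#' Remove miRNAs with pervasive zeros
#'
#' Drops miRNAs for which strictly more than 70% of samples have zero
#' expression.
#'
#' @param expr Wide expression tibble (miRNA rows).
#' @return Filtered expression tibble.
#' @export
filter_mirna <- function(expr) {
  validate_expr(expr)
  m <- expr_matrix(expr)
  zero_frac <- rowMeans(m == 0)
  keep <- zero_frac <= 0.70
  message("miRNA zero filter (>70% zeros removed): ", sum(keep), " of ",
          nrow(m), " retained")
  expr[keep, , drop = FALSE]
}
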