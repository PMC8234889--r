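#' Paired tumor-vs-normal differential expression
#'
#' For each gene, computes the per-patient paired difference
#' `d = log2(tumor + 1) - log2(normal + 1)`, takes the mean difference as
#' the log2 fold change, tests it against zero with a one-sample t-test,
#' and adjusts p-values across genes by Benjamini--Hochberg. A gene is
#' called `up` when log2FC > `lfc_threshold` and adjusted p < `alpha`,
#' `down` symmetrically.
#'
#' This is a deliberately simple paired-design caller on the log scale —
#' no count-level negative-binomial model, dispersion shrinkage or
#' size-factor normalization — and the output carries that note in its
#' `method` attribute (written as a header comment by [write_deg_tsv()]).
#'
#' @param normal,tumor Wide expression tibbles with identical genes and
#'   identical sample IDs (the patient pairing key).
#' @param lfc_threshold Absolute log2-fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return Tibble of class `deg_result`: `gene_id`, `log2fc`, `p_value`,
#'   `p_adj`, `call`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 30, n_genes = 60, seed = 3))
#' degs <- paired_deg(cohort$normal_expr, cohort$tumor_expr)
#' dplyr::count(degs, call)
#' @export
paired_deg <- function(normal, tumor, lfc_threshold = 2, alpha = 0.01) {
  validate_expr(normal)
  validate_expr(tumor)
  if (!identical(sort(normal$gene_id), sort(tumor$gene_id))) {
    stop("normal and tumor tables must contain the same genes", call. = FALSE)
  }
  off <- c(setdiff(sample_ids(normal), sample_ids(tumor)),
           setdiff(sample_ids(tumor), sample_ids(normal)))
  if (length(off) > 0) {
    stop("unpaired sample(s): ", paste(off, collapse = ", "), call. = FALSE)
  }
  mn <- expr_matrix(normal)
  mt <- expr_matrix(tumor)[rownames(mn), colnames(mn), drop = FALSE]
  d <- log2(mt + 1) - log2(mn + 1)
  n <- ncol(d)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)

  lfc <- unname(rowMeans(d))
  s <- unname(apply(d, 1, stats::sd))
  tval <- lfc / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(tval), df = n - 1)
  p[s == 0] <- ifelse(lfc[s == 0] == 0, 1, 0)  # exact ties / exact shifts
  padj <- benjamini_hochberg(p)

  call <- rep("none", nrow(d))
  call[lfc > lfc_threshold & padj < alpha] <- "up"
  call[lfc < -lfc_threshold & padj < alpha] <- "down"
  out <- tibble::tibble(gene_id = rownames(d), log2fc = lfc, p_value = p,
                        p_adj = padj, call = call)
  attr(out, "method") <-
    "paired one-sample t-test on log2(x+1) differences; not a count-model caller"
  attr(out, "thresholds") <- list(lfc = lfc_threshold, alpha = alpha)
  class(out) <- c("deg_result", class(out))
  out
}

#' Benjamini--Hochberg step-up adjustment
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values (monotone step-up, capped at 1).
#' @export
benjamini_hochberg <- function(pvals) {
  stopifnot(is.numeric(pvals), all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Write a DEG table as TSV with a method header
#'
#' @param degs A [paired_deg()] result.
#' @param path Output path.
#' @export
write_deg_tsv <- function(degs, path) {
  writeLines(paste0("# ", attr(degs, "method")), path)
  readr::write_tsv(tibble::as_tibble(degs), path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}
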