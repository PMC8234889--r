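#' Principal components of an expression matrix
#'
#' Sample-space principal components of the gene-standardized expression
#' matrix (each gene row centered and scaled to unit variance before the
#' decomposition). Constant gene rows carry no information and are dropped
#' with a message. Used as nuisance covariates in the PC-adjusted age
#' regression.
#'
#' @param expr Wide expression tibble.
#' @param k Maximum number of components (default 10); reduced to
#'   `n_samples - 1` with a warning when fewer samples are available.
#' @param log2_transform Apply `log2(x + 1)` before standardizing.
#' @return Object of class `pc_scores`: list with `scores` (tibble
#'   `sample_id`, `PC1`, ...) and `var_explained` (fractions).
#' @export
compute_pcs <- function(expr, k = 10, log2_transform = FALSE) {
  validate_expr(expr)
  m <- expr_matrix(expr)
  if (log2_transform) m <- log2(m + 1)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    message(sum(sds == 0), " constant gene row(s) dropped before PCA")
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no variable genes left for PCA", call. = FALSE)
  n <- ncol(m)
  if (n - 1 < k) {
    warning("only ", n, " samples: reducing PCs from ", k, " to ", n - 1,
            call. = FALSE)
    k <- n - 1
  }
  z <- t(scale(t(m)))
  pc <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  structure(list(
    scores = tibble::as_tibble(scores, rownames = "sample_id"),
    var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  ), class = "pc_scores")
}

#' Select principal components uncorrelated with age
#'
#' Keeps the components whose Pearson correlation test against age has
#' p > 0.05, so that adjusting for them cannot absorb the age signal
#' itself. An empty selection is allowed (the adjusted model then reduces
#' to the age-only model).
#'
#' @param pcs A [compute_pcs()] result.
#' @param ages Numeric vector of ages, aligned with the score rows.
#' @param alpha Level of the correlation test (components with p above it
#'   are kept).
#' @return Integer vector of selected component indices.
#' @export
select_pcs <- function(pcs, ages, alpha = 0.05) {
  stopifnot(inherits(pcs, "pc_scores"))
  s <- as.matrix(pcs$scores[, -1, drop = FALSE])
  stopifnot(length(ages) == nrow(s))
  p <- apply(s, 2, function(v) stats::cor.test(v, ages)$p.value)
  keep <- which(p > alpha)
  if (length(keep) == 0) {
    message("no age-independent PCs: adjusted model reduces to age-only model")
  }
  unname(keep)
}

# Vectorized OLS of Y (n x G) on design X (n x p, age in column 2).
# Returns per-gene intercept, age coefficient, its SE and two-sided t p-value.
ols_age <- function(Y, X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- nrow(X) - ncol(X)
  if (df <= 0) stop("more parameters than samples", call. = FALSE)
  beta <- qr.coef(qx, Y)
  rss <- colSums((Y - X %*% beta)^2)
  v_age <- chol2inv(chol(crossprod(X)))[2, 2]
  se <- sqrt(rss / df * v_age)
  tval <- beta[2, ] / se
  p <- 2 * stats::pt(-abs(tval), df)
  # zero-residual degenerate fits: an exact age relation is perfectly
  # significant, a constant response carries no test at all
  if (any(se == 0)) {
    p[se == 0] <- ifelse(beta[2, se == 0] == 0, NA_real_, 0)
  }
  list(intercept = beta[1, ], gamma = beta[2, ], se = se, p = p,
       rss = rss, df = df)
}

#' Fit the age-only and PC-adjusted regressions for one transcript
#'
#' M1 regresses expression on age alone; M2 adds the selected
#' age-independent principal components. Both are ordinary least squares;
#' the age coefficient's p-value is a two-sided t-test.
#'
#' @param y Per-sample expression vector (already on the modeling scale).
#' @param ages Ages, years.
#' @param pcs_selected Optional numeric matrix (samples x selected PCs);
#'   `NULL` or zero columns makes M2 identical to M1.
#' @return List with elements `m1` and `m2`, each of class `age_fit`
#'   with fields `intercept`, `gamma`, `se`, `p`, `rss`, `df`.
#' @export
fit_age_models <- function(y, ages, pcs_selected = NULL) {
  stopifnot(length(y) == length(ages), !anyNA(y), !anyNA(ages))
  Y <- cbind(y)
  X1 <- cbind(`(Intercept)` = 1, age = ages)
  f1 <- ols_age(Y, X1)
  if (is.null(pcs_selected) || NCOL(pcs_selected) == 0) {
    f2 <- f1
  } else {
    pcm <- as.matrix(pcs_selected)
    if (is.null(colnames(pcm))) colnames(pcm) <- paste0("PC", seq_len(ncol(pcm)))
    f2 <- ols_age(Y, cbind(X1, pcm))
  }
  fit1 <- structure(lapply(f1, unname), class = "age_fit")
  fit2 <- structure(lapply(f2, unname), class = "age_fit")
  list(m1 = fit1, m2 = fit2)
}

# shared engine: expression tibble -> per-gene dual-model stats (base list)
aging_scan <- function(m, ages, k = 10, alpha = 0.05, pc_alpha = 0.05) {
  Y <- t(m)  # samples x genes
  X1 <- cbind(`(Intercept)` = 1, age = ages)
  f1 <- ols_age(Y, X1)

  pcs <- compute_pcs(as_expr_tbl(m), k = k)
  sel <- select_pcs(pcs, ages, alpha = pc_alpha)
  if (length(sel) > 0) {
    pcm <- as.matrix(pcs$scores[, 1 + sel, drop = FALSE])
    f2 <- ols_age(Y, cbind(X1, pcm))
  } else {
    f2 <- f1
  }
  dir <- rep("none", nrow(m))
  ok <- !is.na(f1$p) & !is.na(f2$p) & f1$p < alpha & f2$p < alpha &
    sign(f1$gamma) == sign(f2$gamma)
  dir[ok & f2$gamma > 0] <- "increasing"
  dir[ok & f2$gamma < 0] <- "decreasing"
  list(gamma_m1 = unname(f1$gamma), p_m1 = unname(f1$p),
       gamma_m2 = unname(f2$gamma), p_m2 = unname(f2$p),
       direction = dir, pcs_selected = sel)
}

#' Identify aging-related transcripts with dual regression models
#'
#' Per transcript, fits the age-only model (M1) and the PC-adjusted model
#' (M2, using only PCs not correlated with age) and calls a transcript
#' aging-related when the age coefficient has p < `alpha` in **both**
#' models with agreeing signs; the direction (increasing/decreasing with
#' age) is taken from the adjusted model. No multiple-testing correction is
#' applied: the published procedure uses the raw dual p < 0.05 rule, and the
#' bootstrap stability filter ([bootstrap_stability()]) is the guard against
#' fragile calls.
#'
#' @param expr Wide expression tibble (preprocessed).
#' @param ages Ages (years) aligned with the sample columns.
#' @param alpha Per-model significance level for the age coefficient.
#' @param k Number of candidate PCs.
#' @param log2_transform Model `log2(x + 1)` rather than the raw scale
#'   (default TRUE; FPKM-like units are heavy-tailed).
#' @return A tibble of class `aging_result`: `gene_id`, `gamma_m1`, `p_m1`,
#'   `gamma_m2`, `p_m2`, `direction`. Attributes: `pcs_selected`, `alpha`,
#'   `log2_transform`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 60, n_genes = 80, seed = 2))
#' aging <- select_aging_transcripts(cohort$normal_expr,
#'                                   cohort$clinical$age_years)
#' dplyr::count(aging, direction)
#' @export
select_aging_transcripts <- function(expr, ages, alpha = 0.05, k = 10,
                                     log2_transform = TRUE) {
  validate_expr(expr)
  m <- expr_matrix(expr)
  stopifnot(length(ages) == ncol(m))
  if (log2_transform) m <- log2(m + 1)
  sc <- aging_scan(m, ages, k = k, alpha = alpha)
  out <- tibble::tibble(
    gene_id = rownames(m),
    gamma_m1 = sc$gamma_m1, p_m1 = sc$p_m1,
    gamma_m2 = sc$gamma_m2, p_m2 = sc$p_m2,
    direction = sc$direction
  )
  attr(out, "pcs_selected") <- sc$pcs_selected
  attr(out, "alpha") <- alpha
  attr(out, "log2_transform") <- log2_transform
  class(out) <- c("aging_result", class(out))
  out
}

#' Bootstrap stability of aging-transcript calls
#'
#' Repeats the dual-model selection on `B` bootstrap resamples of the
#' samples. For a transcript selected in the full data, stability is the
#' fraction of resamples in which it is selected with the same direction;
#' transcripts below `retain_frac` are demoted to direction `none`. For
#' transcripts not selected in the full data the larger of the two
#' directional fractions is reported as a diagnostic.
#'
#' @inheritParams select_aging_transcripts
#' @param B Number of bootstrap resamples.
#' @param retain_frac Minimum stability to retain a call.
#' @param seed Seed for the resampling.
#' @return An `aging_result` tibble with columns `stability` and
#'   `direction` (post-demotion); the pre-bootstrap call is kept in
#'   `direction_full`.
#' @export
bootstrap_stability <- function(expr, ages, B = 100, retain_frac = 0.5,
                                seed = 1, alpha = 0.05, k = 10,
                                log2_transform = TRUE) {
  stopifnot(B >= 1, retain_frac >= 0, retain_frac <= 1)
  res <- select_aging_transcripts(expr, ages, alpha = alpha, k = k,
                                  log2_transform = log2_transform)
  m <- expr_matrix(expr)
  if (log2_transform) m <- log2(m + 1)
  n <- ncol(m)

  set.seed(as.integer(seed))
  n_up <- n_dn <- integer(nrow(m))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    mb <- m[, idx, drop = FALSE]
    colnames(mb) <- sprintf("b%04d", seq_len(n))  # resampled IDs must be unique
    sc <- suppressMessages(
      aging_scan(mb, ages[idx], k = k, alpha = alpha)
    )
    n_up <- n_up + (sc$direction == "increasing")
    n_dn <- n_dn + (sc$direction == "decreasing")
  }
  stability <- ifelse(res$direction == "increasing", n_up / B,
               ifelse(res$direction == "decreasing", n_dn / B,
                      pmax(n_up, n_dn) / B))
  res$direction_full <- res$direction
  res$stability <- stability
  res$direction[res$direction != "none" & stability < retain_frac] <- "none"
  attr(res, "bootstrap") <- list(B = B, retain_frac = retain_frac, seed = seed)
  res
}

#' Per-sample expression index over a gene set
#'
#' The increasing (decreasing) index is the per-sample average expression
#' over the age-upregulated (age-downregulated) transcripts. Modes:
#' `raw` averages the stored values; `log2` averages `log2(x + 1)`;
#' `zscore` (default) averages per-gene z-scores of `log2(x + 1)`, so no
#' single highly expressed gene dominates.
#'
#' @param expr Wide expression tibble.
#' @param gene_set Character vector of gene IDs (non-empty, all present).
#' @param mode One of `"zscore"`, `"log2"`, `"raw"`.
#' @return Tibble `sample_id`, `index`.
#' @export
compute_index <- function(expr, gene_set, mode = c("zscore", "log2", "raw")) {
  mode <- match.arg(mode)
  validate_expr(expr)
  if (length(gene_set) == 0) stop("empty gene set", call. = FALSE)
  missing <- setdiff(gene_set, expr$gene_id)
  if (length(missing) > 0) {
    stop("gene(s) absent from expression table: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  m <- expr_matrix(expr)[unique(gene_set), , drop = FALSE]
  if (mode %in% c("log2", "zscore")) m <- log2(m + 1)
  if (mode == "zscore") {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0)) {
      message(sum(sds == 0), " constant gene(s) contribute 0 to the z-score index")
      sds[sds == 0] <- Inf
    }
    m <- (m - rowMeans(m)) / sds
  }
  tibble::tibble(sample_id = colnames(m), index = unname(colMeans(m)))
}

#' @export
autoplot.aging_result <- function(object, ...) {
  df <- dplyr::mutate(tibble::as_tibble(object),
                      direction = factor(.data$direction,
                                         c("increasing", "decreasing", "none")))
  ggplot2::ggplot(df, ggplot2::aes(.data$gamma_m2, -log10(.data$p_m2),
                                   colour = .data$direction)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(increasing = "#D55E00", decreasing = "#0072B2",
                 none = "grey70"), drop = FALSE) +
    ggplot2::labs(x = "age coefficient (PC-adjusted model)",
                  y = expression(-log[10] ~ p),
                  colour = "direction") +
    ggplot2::theme_minimal()
}

#' @export
glance.aging_result <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_increasing = sum(x$direction == "increasing"),
    n_decreasing = sum(x$direction == "decreasing"),
    n_pcs_adjusted = length(attr(x, "pcs_selected")),
    alpha = attr(x, "alpha")
  )
}
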