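#' Area under the ROC curve
#'
#' Rank (Mann--Whitney) formulation: the probability that a random positive
#' scores above a random negative, with ties counting one half.
#'
#' @param scores Numeric predictions.
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1),
            !anyNA(scores))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated cross-validated logistic-regression AUC
#'
#' For each repetition, samples a fold assignment (stratified by class by
#' default), fits a logistic regression on the training folds, pools the
#' held-out predicted probabilities across folds, and computes a single
#' AUC from the pooled predictions. Pooling — never per-fold AUCs — keeps
#' small or single-class test folds well-defined.
#'
#' @param features Numeric matrix or data frame, samples x predictors
#'   (1 or 2 columns).
#' @param status Binary outcome vector.
#' @param folds Number of CV folds.
#' @param reps Number of repetitions.
#' @param seed Seed; the AUC vector is deterministic given it.
#' @param stratify Stratify fold assignment by class.
#' @param config_name Label for reporting.
#' @return Object of class `prediction_result`: list with `config`,
#'   `aucs` (length `reps`), `mean_auc`, `sd_auc`, `folds`, `reps`, `seed`.
#' @export
cv_logistic_auc <- function(features, status, folds = 5, reps = 1000,
                            seed = 1, stratify = TRUE,
                            config_name = "features") {
  X <- as.matrix(features)
  storage.mode(X) <- "double"
  status <- as.integer(status)
  n <- length(status)
  stopifnot(nrow(X) == n, all(status %in% 0:1), !anyNA(X))
  if (ncol(X) > 2) stop("at most 2 predictors supported", call. = FALSE)
  if (min(sum(status), sum(1 - status)) < folds) {
    stop("each class needs at least `folds` members", call. = FALSE)
  }

  set.seed(as.integer(seed))
  Xd <- cbind(1, X)
  aucs <- vapply(seq_len(reps), function(r) {
    fold <- integer(n)
    if (stratify) {
      for (cl in 0:1) {
        idx <- sample(which(status == cl))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
    } else {
      fold <- sample(rep_len(seq_len(folds), n))
    }
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      test <- fold == f
      fit <- suppressWarnings(
        stats::glm.fit(Xd[!test, , drop = FALSE], status[!test],
                       family = stats::binomial())
      )
      eta <- Xd[test, , drop = FALSE] %*% stats::coef(fit)
      pred[test] <- stats::plogis(eta)
    }
    roc_auc(pred, status)
  }, numeric(1))

  structure(list(config = config_name, aucs = aucs,
                 mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
                 folds = folds, reps = reps, seed = seed),
            class = "prediction_result")
}

#' @export
print.prediction_result <- function(x, ...) {
  cat(sprintf("CV logistic AUC [%s]: mean %.3f (sd %.3f) over %d x %d-fold\n",
              x$config, x$mean_auc, x$sd_auc, x$reps, x$folds))
  invisible(x)
}

#' @export
tidy.prediction_result <- function(x, ...) {
  tibble::tibble(config = x$config, rep = seq_along(x$aucs), auc = x$aucs)
}

#' @export
glance.prediction_result <- function(x, ...) {
  tibble::tibble(config = x$config, mean_auc = x$mean_auc,
                 sd_auc = x$sd_auc, folds = x$folds, reps = x$reps)
}

#' Compare the five survival-prediction feature sets
#'
#' Builds the five feature configurations — mean tumor expression of
#' down- and up-regulated DEGs, the decreasing and increasing indices in
#' normal tissue, and the combination of the up-DEG mean with the
#' increasing index — and runs [cv_logistic_auc()] on each with vital
#' status as the outcome. The increasing and decreasing indices are never
#' placed in one model (they are strongly correlated; multicollinearity
#' would dilute both).
#'
#' @param normal,tumor Wide expression tibbles (samples aligned with
#'   `clinical`).
#' @param clinical Clinical table with `event` (vital status: 1 deceased).
#' @param aging An `aging_result` with `direction` calls.
#' @param degs A `deg_result` with `call`s.
#' @param folds,reps,seed Passed to [cv_logistic_auc()].
#' @param mode Index mode for the aging indices.
#' @return Tibble of class `feature_comparison`: `config`, `mean_auc`,
#'   `sd_auc`, `folds`, `reps` plus a list column `aucs`, ranked by mean
#'   AUC.
#' @export
compare_feature_sets <- function(normal, tumor, clinical, aging, degs,
                                 folds = 5, reps = 1000, seed = 1,
                                 mode = "zscore") {
  status <- as.integer(clinical$event)
  ids <- sample_order(clinical)

  feat <- function(expr, genes, mode) {
    idx <- compute_index(expr, genes, mode = mode)
    idx$index[match(ids, idx$sample_id)]
  }
  sets <- list(
    down_DEG_tumor_mean = degs$gene_id[degs$call == "down"],
    up_DEG_tumor_mean = degs$gene_id[degs$call == "up"],
    decreasing_index_normal = aging$gene_id[aging$direction == "decreasing"],
    increasing_index_normal = aging$gene_id[aging$direction == "increasing"]
  )
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    stop("empty gene set(s) for: ", paste(empty, collapse = ", "),
         call. = FALSE)
  }
  deg_in_tumor <- function(g) intersect(g, tumor$gene_id)
  cols <- list(
    down_DEG_tumor_mean = feat(tumor, deg_in_tumor(sets$down_DEG_tumor_mean), "log2"),
    up_DEG_tumor_mean = feat(tumor, deg_in_tumor(sets$up_DEG_tumor_mean), "log2"),
    decreasing_index_normal = feat(normal, sets$decreasing_index_normal, mode),
    increasing_index_normal = feat(normal, sets$increasing_index_normal, mode)
  )
  configs <- c(names(cols), "combo_upDEG_plus_increasing")
  results <- purrr::imap(cols, function(v, nm) {
    cv_logistic_auc(cbind(v), status, folds = folds, reps = reps,
                    seed = seed, config_name = nm)
  })
  results$combo_upDEG_plus_increasing <- cv_logistic_auc(
    cbind(up_DEG = cols$up_DEG_tumor_mean,
          incr = cols$increasing_index_normal),
    status, folds = folds, reps = reps, seed = seed,
    config_name = "combo_upDEG_plus_increasing"
  )

  out <- purrr::map_dfr(results[configs], function(r) {
    tibble::tibble(config = r$config, mean_auc = r$mean_auc,
                   sd_auc = r$sd_auc, folds = r$folds, reps = r$reps,
                   aucs = list(r$aucs))
  })
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_auc))
  class(out) <- c("feature_comparison", class(out))
  out
}

#' @export
autoplot.feature_comparison <- function(object, ...) {
  df <- tidyr::unnest(
    dplyr::select(tibble::as_tibble(object), "config", "aucs"),
    "aucs"
  )
  df$config <- factor(df$config, levels = object$config)
  ggplot2::ggplot(df, ggplot2::aes(.data$config, .data$aucs)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "grey85") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = NULL, y = "cross-validated AUC") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
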