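#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ x` by partial likelihood (Efron tie handling
#' by default) and reports the hazard ratio with its Wald p-value. By
#' default the covariate is standardized first so hazard ratios are per SD
#' — index covariates have no natural unit.
#'
#' @param clinical Data frame with `time_days` (or `time`) and `event`.
#' @param x Per-sample numeric covariate, aligned with `clinical` rows.
#' @param standardize Scale `x` to unit SD before fitting.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param term Covariate label for reporting.
#' @return Object of class `cox_fit`: list with `term`, `coef`, `hr`,
#'   `se`, `p_value`, `n`, `n_event`, `standardized`, `ties`.
#' @export
fit_cox_univariate <- function(clinical, x, standardize = TRUE,
                               ties = c("efron", "breslow"),
                               term = substr(deparse1(substitute(x)), 1, 40)) {
  ties <- match.arg(ties)
  tm <- clinical_times(clinical)
  stopifnot(length(x) == nrow(clinical))
  if (anyNA(x) || any(!is.finite(x))) {
    stop("covariate contains missing or non-finite values", call. = FALSE)
  }
  if (sum(tm$event) < 2) stop("need at least 2 events", call. = FALSE)
  if (stats::sd(x) == 0) {
    stop("covariate is constant: no information for the Cox model",
         call. = FALSE)
  }
  if (standardize) x <- as.numeric(scale(x))
  fit <- survival::coxph(survival::Surv(tm$time, tm$event) ~ x, ties = ties)
  beta <- unname(stats::coef(fit))
  if (!is.finite(beta) || abs(beta) > 20) {
    stop("Cox fit did not converge to a finite coefficient (beta = ",
         signif(beta, 3), " after ", fit$iter, " iterations)", call. = FALSE)
  }
  se <- sqrt(unname(diag(stats::vcov(fit))))
  structure(list(
    term = term, coef = beta, hr = exp(beta), se = se,
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    n = fit$n, n_event = fit$nevent,
    standardized = standardize, ties = ties
  ), class = "cox_fit")
}

clinical_times <- function(clinical) {
  tcol <- if ("time_days" %in% names(clinical)) "time_days" else "time"
  stopifnot(tcol %in% names(clinical), "event" %in% names(clinical))
  time <- clinical[[tcol]]
  event <- clinical[["event"]]
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  list(time = time, event = event)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Univariate Cox fit (", x$ties, " ties): ", x$term,
      if (x$standardized) " [per SD]" else "", "\n", sep = "")
  cat(sprintf("  HR = %.3f  (coef %.3f, se %.3f),  Wald p = %.3g,  %d events / %d\n",
              x$hr, x$coef, x$se, x$p_value, x$n_event, x$n))
  invisible(x)
}

#' @export
tidy.cox_fit <- function(x, ...) {
  tibble::tibble(term = x$term, estimate = x$coef, hazard_ratio = x$hr,
                 std.error = x$se, p.value = x$p_value)
}

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_event = x$n_event, ties = x$ties,
                 standardized = x$standardized)
}

#' Median split of a continuous covariate
#'
#' Dichotomizes at the sample median; ties at the median go to the low
#' group, so `low = {x <= median}` and `high = {x > median}`.
#'
#' @param x Numeric vector, length >= 2.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(x) {
  stopifnot(length(x) >= 2, !anyNA(x))
  if (max(x) == min(x)) {
    stop("all values identical: cannot form two groups", call. = FALSE)
  }
  factor(ifelse(x <= stats::median(x), "low", "high"),
         levels = c("low", "high"))
}

#' Kaplan--Meier curves by group
#'
#' Product-limit estimate of survival per group, returned tidily with a
#' time-0 anchor row per group.
#'
#' @param clinical Data frame with `time_days` (or `time`) and `event`.
#' @param groups Factor/character of group labels, one per row.
#' @return Tibble of class `km_curves`: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`.
#' @export
km_estimate <- function(clinical, groups) {
  tm <- clinical_times(clinical)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(clinical))
  if (any(table(groups) == 0)) stop("empty group", call. = FALSE)
  fit <- survival::survfit(survival::Surv(tm$time, tm$event) ~ groups)
  if (is.null(fit$strata)) {
    grp <- rep(levels(groups)[1], length(fit$time))
  } else {
    grp <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble::tibble(group = grp, time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, surv = fit$surv)
  anchor <- dplyr::summarise(dplyr::group_by(out, .data$group),
                             time = 0, n_risk = max(.data$n_risk),
                             n_event = 0L, surv = 1, .groups = "drop")
  out <- dplyr::arrange(dplyr::bind_rows(anchor, out), .data$group,
                        .data$time)
  class(out) <- c("km_curves", class(out))
  out
}

#' @export
autoplot.km_curves <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time, .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' @param clinical Data frame with `time_days` (or `time`) and `event`.
#' @param groups Two-level grouping, one label per row.
#' @return List with `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(clinical, groups) {
  tm <- clinical_times(clinical)
  groups <- droplevels(as.factor(groups))
  stopifnot(length(groups) == nrow(clinical))
  if (nlevels(groups) != 2) stop("log-rank test needs exactly 2 groups",
                                 call. = FALSE)
  if (sum(tm$event) < 1) stop("no events", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(tm$time, tm$event) ~ groups)
  list(statistic = unname(sd$chisq), df = 1,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value: the total hypergeometric probability of all
#' tables (at the observed margins) no more probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `p_value` and the conditional odds-ratio `estimate`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  ft <- stats::fisher.test(table)
  list(p_value = ft$p.value, estimate = unname(ft$estimate))
}

#' Welch two-group t-test
#'
#' @param x Numeric values.
#' @param group Two-level grouping, one label per value; each group needs
#'   at least 2 observations.
#' @param var_equal Use the pooled-variance test instead of Welch.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
two_group_ttest <- function(x, group, var_equal = FALSE) {
  group <- droplevels(as.factor(group))
  stopifnot(length(x) == length(group), nlevels(group) == 2)
  if (any(table(group) < 2)) stop("each group needs >= 2 values",
                                  call. = FALSE)
  tt <- stats::t.test(x ~ group, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
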