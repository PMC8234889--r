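# Independent oracles used across the suite. Each recomputes a quantity
# from its textbook definition, never through the package's own code path.

# least squares by explicit normal equations, with t-test p for column 2
ols_oracle <- function(y, X) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * diag(solve(XtX)))
  tval <- beta / se
  list(beta = drop(beta), se = se,
       p = 2 * pt(-abs(drop(tval)), df), df = df)
}

# two-group log-rank by direct observed-minus-expected summation
logrank_oracle <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  times <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(statistic = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# two-sided Fisher p by full hypergeometric enumeration at fixed margins
fisher_oracle <- function(tab) {
  m <- sum(tab[1, ])
  n <- sum(tab[2, ])
  k <- sum(tab[, 1])
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  sum(d[d <= dhyper(x, m, n, k) * (1 + 1e-7)])
}

# Benjamini-Hochberg from the step-up definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# AUC by trapezoidal integration of the empirical ROC curve
auc_trapezoid <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Cox partial likelihood (no ties assumed) for brute-force maximization
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# adjusted Rand index between two labelings (NA = its own singleton)
ari <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  a[is.na(a)] <- paste0(".na", seq_along(a))[is.na(a)]
  b[is.na(b)] <- paste0(".nb", seq_along(b))[is.na(b)]
  mclust::adjustedRandIndex(a, b)
}

# small wide expression tibble from a matrix without dimnames
expr_fixture <- function(m, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(m)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, samples)
  as_expr_tbl(m)
}
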