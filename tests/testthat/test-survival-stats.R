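test_that("Cox fit maximizes the partial likelihood and behaves under negation", {
  # 4-subject no-tie fixture with a finite maximizer: compare against
  # brute-force maximization of the hand-written partial likelihood
  cl <- tibble::tibble(sample_id = paste0("s", 1:4),
                       time_days = c(1, 2, 3, 4), event = c(1, 1, 1, 0))
  x <- c(1, 0, 1, 0)
  fit <- fit_cox_univariate(cl, x, standardize = FALSE)
  oracle <- optimize(cox_partial_loglik, c(-10, 10), maximum = TRUE,
                     tol = 1e-10, time = cl$time_days, event = cl$event,
                     x = x)$maximum
  expect_equal(fit$coef, oracle, tolerance = 1e-6)

  # sign flip: coefficient negates, hazard ratio inverts
  fit_neg <- fit_cox_univariate(cl, -x, standardize = FALSE)
  expect_equal(fit_neg$coef, -fit$coef, tolerance = 1e-8)
  expect_equal(fit_neg$hr, 1 / fit$hr, tolerance = 1e-8)

  # degenerate inputs are refused with clear messages
  expect_error(fit_cox_univariate(cl, rep(1, 4)), "constant")
  cl0 <- tibble::tibble(sample_id = "s1", time_days = 1, event = 0)
  expect_error(fit_cox_univariate(dplyr::bind_rows(cl0, cl0),
                                  c(0, 1)), "events")

  td <- tidy(fit)
  expect_equal(td$hazard_ratio, exp(td$estimate))
})

test_that("Cox recovers a planted hazard ratio per index SD", {
  co <- simulate_cohort(sim_config(n_samples = 400, n_genes = 100,
                                   n_aging_up = 30, n_aging_down = 20,
                                   n_deg_up = 10, n_deg_down = 10,
                                   log_hr_per_index_sd = log(2),
                                   censor_rate = 0.3, seed = 10))
  fit <- fit_cox_univariate(co$clinical, co$true_index)
  expect_gt(fit$hr, 1.7)
  expect_lt(fit$hr, 2.4)
  expect_lt(fit$p_value, 1e-4)
  # censoring realized near its target
  expect_equal(1 - mean(co$clinical$event), 0.3, tolerance = 0.07)
})

test_that("median split follows the tie-to-low rule", {
  expect_identical(as.character(median_split(c(1, 2, 3, 4))),
                   c("low", "low", "high", "high"))
  expect_identical(as.character(median_split(c(1, 2, 3))),
                   c("low", "low", "high"))
  expect_identical(as.character(median_split(c(1, 2, 2, 2, 5))),
                   c("low", "low", "low", "low", "high"))
  expect_error(median_split(rep(3, 5)), "identical")
})

test_that("Kaplan-Meier estimate matches the product-limit computation", {
  cl <- tibble::tibble(sample_id = paste0("s", 1:3),
                       time_days = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_estimate(cl, rep("all", 3))
  expect_equal(km$surv[km$time > 0], c(2 / 3, 1 / 3, 0))
  expect_equal(km$surv[km$time == 0], 1)

  # all censored: survival stays at 1
  cl2 <- dplyr::mutate(cl, event = 0)
  expect_true(all(km_estimate(cl2, rep("all", 3))$surv == 1))

  # censoring after the last event leaves the curve at event times unchanged
  cl3 <- dplyr::bind_rows(cl, tibble::tibble(sample_id = "s4",
                                             time_days = 10, event = 0))
  km3 <- km_estimate(cl3, rep("all", 4))
  expect_equal(km3$surv[km3$time %in% 1:3], c(3 / 4, 2 / 4, 1 / 4))

  # with no censoring the KM curve is the empirical survival function
  set.seed(11)
  t5 <- rexp(40)
  cl5 <- tibble::tibble(sample_id = paste0("s", 1:40), time_days = t5,
                        event = 1)
  km5 <- km_estimate(cl5, rep("all", 40))
  at <- km5$time[km5$time > 0]
  expect_equal(km5$surv[km5$time > 0], vapply(at, function(u) mean(t5 > u), 0))
})

test_that("log-rank test matches the hypergeometric summation oracle", {
  # duplicated data in both groups: no difference at all
  cl <- tibble::tibble(sample_id = paste0("s", 1:6),
                       time_days = rep(c(1, 2, 3), 2),
                       event = rep(c(1, 1, 0), 2))
  lr0 <- logrank_test(cl, rep(c("a", "b"), each = 3))
  expect_equal(lr0$statistic, 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-12)

  # 8-subject fixture against direct observed-minus-expected summation
  cl8 <- tibble::tibble(sample_id = paste0("s", 1:8),
                        time_days = c(1, 3, 4, 6, 2, 5, 7, 9),
                        event = c(1, 1, 0, 1, 1, 0, 1, 1))
  g8 <- rep(c("a", "b"), each = 4)
  lr <- logrank_test(cl8, g8)
  oracle <- logrank_oracle(cl8$time_days, cl8$event, g8)
  expect_equal(lr$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(lr$p_value, oracle$p, tolerance = 1e-10)

  # planted hazard ratio 2.5 with 150 per group: decisive rejection
  set.seed(12)
  n <- 150
  tt <- c(rexp(n, 0.1 * 2.5), rexp(n, 0.1))
  cc <- runif(2 * n, 0, 30)
  clp <- tibble::tibble(sample_id = paste0("s", 1:(2 * n)),
                        time_days = pmin(tt, cc),
                        event = as.integer(tt <= cc))
  expect_lt(logrank_test(clp, rep(c("high", "low"), each = n))$p_value, 0.01)
})

test_that("log-rank p-values are uniform under permuted labels", {
  set.seed(13)
  n <- 60
  tt <- rexp(n, 0.2)
  cc <- runif(n, 0, 12)
  cl <- tibble::tibble(sample_id = paste0("s", 1:n),
                       time_days = pmin(tt, cc), event = as.integer(tt <= cc))
  p <- replicate(300, {
    logrank_test(cl, sample(rep(c("a", "b"), each = n / 2)))$p_value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("Fisher's exact test equals hypergeometric enumeration", {
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p_value, 34 / 70,
               tolerance = 1e-12)
  # zero margin: only one table possible
  expect_equal(fisher_exact(matrix(c(0, 0, 4, 6), 2, byrow = TRUE))$p_value, 1)

  # random tables with small margins against the enumeration oracle
  set.seed(14)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 3), 2)
    if (sum(tab) == 0 || sum(tab) > 12) next
    expect_equal(fisher_exact(tab)$p_value, fisher_oracle(tab),
                 tolerance = 1e-10)
  }
})

test_that("two-group t-test reproduces the Welch formula", {
  x <- c(4.1, 5.2, 6.3, 5.5, 7.0, 8.1, 6.9, 7.7)
  g <- rep(c("a", "b"), each = 4)
  tt <- two_group_ttest(x, g)
  m1 <- mean(x[1:4]); m2 <- mean(x[5:8])
  v1 <- var(x[1:4]); v2 <- var(x[5:8])
  se <- sqrt(v1 / 4 + v2 / 4)
  tstat <- (m1 - m2) / se
  df <- se^4 / ((v1 / 4)^2 / 3 + (v2 / 4)^2 / 3)
  expect_equal(tt$statistic, tstat, tolerance = 1e-10)
  expect_equal(tt$df, df, tolerance = 1e-10)
  expect_equal(tt$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  t0 <- two_group_ttest(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)

  # equal observed variances: Welch agrees with the pooled test
  y <- c(1, 2, 3, 4, 11, 12, 13, 14)
  tw <- two_group_ttest(y, g)
  tp <- two_group_ttest(y, g, var_equal = TRUE)
  expect_equal(tw$statistic, tp$statistic, tolerance = 1e-12)
  expect_equal(tw$p_value, tp$p_value, tolerance = 1e-12)
})
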