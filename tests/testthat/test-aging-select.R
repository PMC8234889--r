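test_that("principal components agree with an SVD oracle", {
  # rank-1 matrix: a single latent factor owns all the variance
  set.seed(1)
  load1 <- rnorm(12)
  fac <- rnorm(30)
  m <- outer(load1, fac) + matrix(rnorm(12 * 30, sd = 1e-4), 12, 30)
  pcs1 <- compute_pcs(expr_fixture(m))
  expect_gt(pcs1$var_explained[1], 0.999)

  # oracle: SVD of the double-centered standardized matrix
  set.seed(2)
  m2 <- matrix(rnorm(20 * 50), 20, 50)
  pcs <- compute_pcs(expr_fixture(m2))
  z <- t(scale(t(m2)))
  x <- scale(t(z), center = TRUE, scale = FALSE)
  sv <- svd(x)
  oracle <- sv$u %*% diag(sv$d)
  got <- as.matrix(pcs$scores[, -1])
  for (j in seq_len(ncol(got))) {
    expect_lt(min(max(abs(got[, j] - oracle[, j])),
                  max(abs(got[, j] + oracle[, j]))), 1e-8)
  }

  # constant rows dropped with a message
  m3 <- rbind(matrix(rnorm(5 * 20), 5, 20), const = rep(7, 20))
  expect_message(compute_pcs(expr_fixture(m3)), "constant")

  # fewer than 11 samples: K reduced with a warning
  expect_warning(p4 <- compute_pcs(expr_fixture(matrix(rnorm(40), 8, 5))),
                 "reducing")
  expect_equal(ncol(p4$scores) - 1, 4)
})

test_that("PC selection excludes age-correlated components", {
  set.seed(3)
  n <- 100
  ages <- runif(n, 30, 80)
  m <- matrix(rnorm(50 * n), 50, n)
  m[1:25, ] <- m[1:25, ] + 2 * rep(ages - mean(ages), each = 25) / sd(ages)
  pcs <- compute_pcs(expr_fixture(m))
  sel <- select_pcs(pcs, ages)
  # the age-dominated leading PC must be excluded
  r1 <- abs(cor(pcs$scores$PC1, ages))
  expect_gt(r1, 0.9)
  expect_false(1 %in% sel)

  # independent noise PCs are retained at roughly the test's level
  set.seed(4)
  keep <- replicate(200, {
    v <- rnorm(n)
    cor.test(v, ages)$p.value > 0.05
  })
  expect_gt(mean(keep), 0.90)
})

test_that("dual regression matches the normal-equation oracle", {
  # exact linear relation recovered exactly
  ages <- seq(30, 79)
  fit <- fit_age_models(2 + 3 * ages, ages)
  expect_equal(fit$m1$gamma, 3, tolerance = 1e-10)
  expect_equal(fit$m1$intercept, 2, tolerance = 1e-8)
  expect_lte(fit$m1$p, 1e-12)  # exact relation: p below machine tolerance

  # random fixture, with PC covariates, against explicit normal equations
  set.seed(5)
  n <- 50
  ages2 <- runif(n, 35, 85)
  pcs <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("PC", 1:3)))
  y <- 1 + 0.05 * ages2 + pcs %*% c(0.5, -0.3, 0.2) + rnorm(n)
  fit2 <- fit_age_models(drop(y), ages2, pcs)
  o1 <- ols_oracle(y, cbind(1, ages2))
  o2 <- ols_oracle(y, cbind(1, ages2, pcs))
  expect_equal(fit2$m1$gamma, unname(o1$beta[2]), tolerance = 1e-8)
  expect_equal(fit2$m1$p, unname(o1$p[2]), tolerance = 1e-8)
  expect_equal(fit2$m2$gamma, unname(o2$beta[2]), tolerance = 1e-8)
  expect_equal(fit2$m2$p, unname(o2$p[2]), tolerance = 1e-8)

  # collinear design names the offending column
  expect_error(fit_age_models(drop(y), ages2, cbind(agecopy = ages2)),
               "collinear")
})

test_that("selection calls planted genes and respects the dual-significance rule", {
  co <- simulate_cohort(sim_config(n_samples = 150, n_genes = 300,
                                   n_aging_up = 30, n_aging_down = 20,
                                   n_deg_up = 0, n_deg_down = 0, seed = 6))
  ag <- suppressMessages(
    select_aging_transcripts(co$normal_expr, co$clinical$age_years))

  true_dir <- ifelse(co$truth$label == "aging_up", "increasing",
                     ifelse(co$truth$label == "aging_down", "decreasing",
                            "none"))
  planted <- true_dir != "none"
  expect_gt(mean(ag$direction[planted] == true_dir[planted]), 0.9)

  # the stated rule holds row by row
  called <- ag$direction != "none"
  expect_true(all((ag$p_m1 < 0.05 & ag$p_m2 < 0.05 &
                     sign(ag$gamma_m1) == sign(ag$gamma_m2))[called]))
  expect_false(any((ag$p_m1 < 0.05 & ag$p_m2 < 0.05 &
                      sign(ag$gamma_m1) == sign(ag$gamma_m2))[!called] &
                     !is.na(ag$p_m1[!called])))
  expect_identical(ag$direction[called],
                   ifelse(ag$gamma_m2[called] > 0, "increasing",
                          "decreasing"))
})

test_that("selection is invariant to sample order and M2 collapses to M1", {
  co <- simulate_cohort(sim_config(n_samples = 40, n_genes = 60,
                                   n_aging_up = 8, n_aging_down = 6,
                                   n_deg_up = 5, n_deg_down = 5, seed = 7))
  ages <- co$clinical$age_years
  ag1 <- suppressMessages(select_aging_transcripts(co$normal_expr, ages))
  perm <- sample(seq_along(ages))
  expr_p <- co$normal_expr[, c(1, 1 + perm)]
  ag2 <- suppressMessages(select_aging_transcripts(expr_p, ages[perm]))
  expect_equal(ag1$gamma_m1, ag2$gamma_m1, tolerance = 1e-10)
  expect_equal(ag1$p_m2, ag2$p_m2, tolerance = 1e-9)
  expect_identical(ag1$direction, ag2$direction)

  # with zero selected PCs the two models are numerically identical
  set.seed(8)
  n <- 60
  ages3 <- runif(n, 30, 80)
  fitz <- fit_age_models(rnorm(n), ages3, NULL)
  expect_identical(fitz$m1, fitz$m2)
})

test_that("bootstrap stability separates deterministic from null signal", {
  set.seed(9)
  n <- 60
  ages <- runif(n, 30, 80)
  exact <- 2^(1 + 0.05 * ages) - 1     # log2(x+1) = 1 + 0.05*age, noiseless
  noisy <- 2^(3 + 0.04 * ages + rnorm(n, sd = 0.5))
  nulls <- 2^matrix(rnorm(200 * n, 5), 200, n)
  m <- rbind(exact = exact, noisy = noisy, nulls)
  e <- expr_fixture(m, genes = c("exact", "noisy", sprintf("null%03d", 1:200)))

  bs <- suppressMessages(suppressWarnings(
    bootstrap_stability(e, ages, B = 50, retain_frac = 0.5, seed = 1)))
  expect_equal(bs$stability[bs$gene_id == "exact"], 1)
  expect_equal(bs$stability[bs$gene_id == "noisy"], 1)
  expect_identical(bs$direction[bs$gene_id == "noisy"], "increasing")
  null_stab <- bs$stability[grepl("^null", bs$gene_id)]
  expect_lt(median(null_stab), 0.2)
  # demotion only ever moves calls to "none"
  expect_true(all(bs$direction[bs$direction_full == "none"] == "none"))
})

test_that("expression index reduces to the documented per-mode formulas", {
  m <- matrix(c(1, 2, 3, 4,
                5, 6, 7, 8,
                2, 4, 8, 16), 3, 4, byrow = TRUE)
  e <- expr_fixture(m, genes = c("a", "b", "c"))

  # single gene, raw mode: the gene's own row
  idx <- compute_index(e, "b", mode = "raw")
  expect_equal(idx$index, c(5, 6, 7, 8))

  # gene order is irrelevant
  expect_equal(compute_index(e, c("a", "c"), mode = "log2")$index,
               compute_index(e, c("c", "a"), mode = "log2")$index)

  # zscore mode against a hand computation
  lz <- log2(m + 1)
  z <- t(apply(lz, 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(compute_index(e, c("a", "b", "c"), mode = "zscore")$index,
               colMeans(z), tolerance = 1e-10)

  expect_error(compute_index(e, character(0)), "empty")
  expect_error(compute_index(e, "zz"), "absent")
})
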