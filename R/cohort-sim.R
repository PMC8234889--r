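#' Configure a synthetic cohort
#'
#' Builds the parameter set for [simulate_cohort()]. The defaults describe a
#' mid-sized solid-tumor cohort: 150 patients with paired normal/tumor
#' expression over 2000 genes, ages drawn from a Normal(61, 14.8) truncated
#' to 20--90 years, 100 genes whose log2 expression drifts linearly with age
#' (60 up, 40 down), 100 planted tumor DEGs, a handful of latent non-age
#' factors that induce principal components, mild zero-inflation, and
#' exponential survival whose hazard rises with the true increasing index.
#'
#' @param n_samples Number of patients (paired normal/tumor samples).
#' @param n_genes Number of genes.
#' @param n_aging_up,n_aging_down Counts of genes whose log2 expression
#'   increases / decreases with age.
#' @param age_mean,age_sd Mean and SD (years) of the age distribution before
#'   truncation.
#' @param age_range Truncation bounds for age, years.
#' @param slope_scale Effect size of the planted age slopes: the per-year
#'   slope is `slope_scale * sd(non-age noise) / sd(age)`, so the population
#'   correlation between age and log2 expression of a planted gene is
#'   `slope_scale / sqrt(1 + slope_scale^2)`. See [slope_scale_for_cor()].
#' @param n_latent Number of latent non-age factors.
#' @param latent_scale SD of the latent-factor loadings (log2 units).
#' @param resid_sd Residual SD of log2 expression.
#' @param zero_inflation_rate Overall fraction of expression entries set to
#'   zero after exponentiation. Dropout is expression-dependent (logistic
#'   in log2 expression, calibrated to this overall rate), so zeros
#'   concentrate in lowly expressed entries as in real RNA-seq data.
#' @param n_deg_up,n_deg_down Counts of planted tumor-vs-normal DEGs.
#' @param deg_log2fc Absolute log2 fold change planted on DEG genes.
#' @param tumor_noise_sd SD of extra per-entry log2 noise in the tumor
#'   matrix (keeps paired differences non-degenerate).
#' @param n_mirna Number of miRNAs for [simulate_mirna()].
#' @param baseline_hazard Baseline hazard, events per year.
#' @param log_hr_per_index_sd Log hazard ratio per SD of the true
#'   (standardized) increasing index.
#' @param censor_rate Target fraction of censored patients; censoring is
#'   independent Uniform(0, c_max) with c_max solved to hit this rate.
#' @param seed Integer seed; fully determines the output.
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_samples = 150, n_genes = 2000,
                       n_aging_up = 60, n_aging_down = 40,
                       age_mean = 61, age_sd = 14.8, age_range = c(20, 90),
                       slope_scale = slope_scale_for_cor(0.35),
                       n_latent = 3, latent_scale = 0.5, resid_sd = 1,
                       zero_inflation_rate = 0.05,
                       n_deg_up = 50, n_deg_down = 50, deg_log2fc = 3,
                       tumor_noise_sd = 0.5,
                       n_mirna = 200,
                       baseline_hazard = 0.1,
                       log_hr_per_index_sd = log(2),
                       censor_rate = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_aging_up = as.integer(n_aging_up), n_aging_down = as.integer(n_aging_down),
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    slope_scale = slope_scale,
    n_latent = as.integer(n_latent), latent_scale = latent_scale,
    resid_sd = resid_sd,
    zero_inflation_rate = zero_inflation_rate,
    n_deg_up = as.integer(n_deg_up), n_deg_down = as.integer(n_deg_down),
    deg_log2fc = deg_log2fc, tumor_noise_sd = tumor_noise_sd,
    n_mirna = as.integer(n_mirna),
    baseline_hazard = baseline_hazard,
    log_hr_per_index_sd = log_hr_per_index_sd,
    censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_samples <= 0 || cfg$n_genes <= 0) {
    stop("n_samples and n_genes must be positive", call. = FALSE)
  }
  if (cfg$n_aging_up < 0 || cfg$n_aging_down < 0 ||
      cfg$n_deg_up < 0 || cfg$n_deg_down < 0) {
    stop("planted gene counts must be non-negative", call. = FALSE)
  }
  if (cfg$n_aging_up + cfg$n_aging_down + cfg$n_deg_up + cfg$n_deg_down >
      cfg$n_genes) {
    stop("planted gene counts exceed n_genes", call. = FALSE)
  }
  for (r in c("zero_inflation_rate", "censor_rate")) {
    if (cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop(r, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (cfg$age_range[1] >= cfg$age_range[2]) {
    stop("age_range must be increasing", call. = FALSE)
  }
  if (cfg$baseline_hazard <= 0) {
    stop("baseline_hazard must be positive", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Slope scale giving a target age--expression correlation
#'
#' Inverts the relation `r = s / sqrt(1 + s^2)` between the simulator's
#' `slope_scale` and the population Pearson correlation of age with a
#' planted gene's log2 expression.
#'
#' @param r Target population correlation, in (-1, 1).
#' @return The `slope_scale` value.
#' @export
slope_scale_for_cor <- function(r) {
  stopifnot(abs(r) < 1)
  r / sqrt(1 - r^2)
}

# SD of a Normal(mean, sd) truncated to [lo, hi]
truncnorm_sd <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  m1 <- (stats::dnorm(a) - stats::dnorm(b)) / z
  v <- 1 + (a * stats::dnorm(a) - b * stats::dnorm(b)) / z - m1^2
  sd * sqrt(v)
}

# inverse-CDF draw from the truncated normal (deterministic given the RNG)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Expression-dependent dropout: entry ij is zeroed with probability
# plogis(x0 - log2expr_ij), with x0 calibrated so the overall zero fraction
# equals `rate`. Low-expression entries drop out preferentially, as in real
# RNA-seq, so planted age correlations on well-expressed genes survive
# measurement.
dropout_zero <- function(x, log2x, rate) {
  if (rate <= 0) return(x)
  if (rate >= 1) { x[] <- 0; return(x) }
  f <- function(x0) mean(stats::plogis(x0 - log2x)) - rate
  x0 <- stats::uniroot(f, c(min(log2x) - 40, max(log2x) + 40), tol = 1e-9)$root
  drop <- stats::runif(length(x)) < stats::plogis(x0 - log2x)
  x[matrix(drop, nrow(x), ncol(x))] <- 0
  x
}

# Uniform(0, cmax) censoring bound hitting the target censor fraction given
# per-subject exponential hazards
censor_bound <- function(lambda, target) {
  pcens <- function(cmax) {
    mean((1 - exp(-lambda * cmax)) / (lambda * cmax)) - target
  }
  stats::uniroot(pcens, c(1e-8, 1e6), tol = 1e-10)$root
}

#' Simulate a paired normal/tumor cohort with planted ground truth
#'
#' Generates log2 expression as intercept + age slope + latent-factor
#' loadings + Gaussian noise, exponentiates, and applies iid zero-inflation.
#' The tumor matrix is the same log2 signal plus planted multiplicative
#' shifts (log2FC +/- `deg_log2fc`) on DEG genes and per-entry noise.
#' Survival times are exponential with hazard
#' `baseline_hazard * exp(log_hr_per_index_sd * z)`, where `z` is the
#' standardized true increasing index (mean of per-gene z-scored log2
#' expression over the aging-up genes), and censoring is independent
#' Uniform(0, c_max) with c_max solved to match `censor_rate`.
#'
#' @param config A [sim_config()].
#' @return An object of class `synthetic_cohort`: a list with wide tibbles
#'   `normal_expr` and `tumor_expr`, a `clinical` tibble
#'   (`sample_id`, `age_years`, `time_days`, `event`, `metastasis`), a
#'   `truth` tibble (`gene_id`, `label`, `true_slope`), the per-sample
#'   standardized `true_index`, and the `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 30, n_genes = 50, seed = 1))
#' dplyr::count(cohort$truth, label)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes

  gene_ids <- sprintf("g%04d", seq_len(g))
  samp_ids <- sprintf("s%03d", seq_len(n))
  label <- rep("null", g)
  idx_up <- seq_len(config$n_aging_up)
  idx_dn <- seq_len(config$n_aging_down) + config$n_aging_up
  idx_du <- seq_len(config$n_deg_up) + config$n_aging_up + config$n_aging_down
  idx_dd <- seq_len(config$n_deg_down) +
    config$n_aging_up + config$n_aging_down + config$n_deg_up
  label[idx_up] <- "aging_up"
  label[idx_dn] <- "aging_down"
  label[idx_du] <- "tumor_DEG_up"
  label[idx_dd] <- "tumor_DEG_down"

  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  sd_age <- truncnorm_sd(config$age_mean, config$age_sd,
                         config$age_range[1], config$age_range[2])

  intercept <- stats::rnorm(g, mean = 6, sd = 1.5)
  loadings <- matrix(stats::rnorm(g * config$n_latent, 0, config$latent_scale),
                     g, config$n_latent)
  noise_sd2 <- config$resid_sd^2 + rowSums(loadings^2)
  slope <- numeric(g)
  slope[idx_up] <- config$slope_scale * sqrt(noise_sd2[idx_up]) / sd_age
  slope[idx_dn] <- -config$slope_scale * sqrt(noise_sd2[idx_dn]) / sd_age

  factors <- matrix(stats::rnorm(n * config$n_latent), n, config$n_latent)
  log2_normal <- intercept +
    outer(slope, age - config$age_mean) +
    loadings %*% t(factors) +
    matrix(stats::rnorm(g * n, 0, config$resid_sd), g, n)
  dimnames(log2_normal) <- list(gene_ids, samp_ids)

  shift <- numeric(g)
  shift[idx_du] <- config$deg_log2fc
  shift[idx_dd] <- -config$deg_log2fc
  log2_tumor <- log2_normal + shift +
    matrix(stats::rnorm(g * n, 0, config$tumor_noise_sd), g, n)

  normal <- dropout_zero(2^log2_normal, log2_normal,
                         config$zero_inflation_rate)
  tumor <- dropout_zero(2^log2_tumor, log2_tumor,
                        config$zero_inflation_rate)

  if (config$n_aging_up > 0) {
    zmat <- t(scale(t(log2_normal[idx_up, , drop = FALSE])))
    true_index <- as.numeric(scale(colMeans(zmat)))
  } else {
    true_index <- rep(0, n)
  }

  lambda <- config$baseline_hazard * exp(config$log_hr_per_index_sd * true_index)
  t_event <- stats::rexp(n, rate = lambda)
  if (config$censor_rate > 0) {
    cmax <- censor_bound(lambda, config$censor_rate)
    t_cens <- stats::runif(n, 0, cmax)
  } else {
    t_cens <- rep(Inf, n)
  }
  event <- as.integer(t_event <= t_cens)
  time_days <- pmin(t_event, t_cens) * 365.25

  metastasis <- stats::rbinom(n, 1, stats::plogis(-1 + 0.5 * true_index))
  metastasis[stats::runif(n) < 0.1] <- NA_integer_

  structure(list(
    normal_expr = as_expr_tbl(normal),
    tumor_expr = as_expr_tbl(tumor),
    clinical = tibble::tibble(
      sample_id = samp_ids, age_years = age,
      time_days = time_days, event = event, metastasis = metastasis
    ),
    truth = tibble::tibble(gene_id = gene_ids, label = label,
                           true_slope = slope),
    true_index = stats::setNames(true_index, samp_ids),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic paired cohort:", x$config$n_samples, "patients,",
      x$config$n_genes, "genes\n")
  cat("  planted:", sum(x$truth$label == "aging_up"), "aging-up,",
      sum(x$truth$label == "aging_down"), "aging-down,",
      sum(grepl("^tumor_DEG", x$truth$label)), "tumor DEGs\n")
  cat("  events:", sum(x$clinical$event), "of", nrow(x$clinical), "\n")
  invisible(x)
}

#' Simulate an RPM-like miRNA expression matrix
#'
#' Positive log-normal matrix with iid zero-inflation, used to exercise the
#' miRNA branch of the preprocessing rules (quantile normalization and the
#' 70% zero filter).
#'
#' @param config A [sim_config()]; uses `n_mirna`, `n_samples`,
#'   `zero_inflation_rate` and `seed`.
#' @return A wide expression tibble (`n_mirna` rows).
#' @export
simulate_mirna <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 101L)
  l <- matrix(stats::rnorm(config$n_mirna * config$n_samples, 4, 2),
              config$n_mirna, config$n_samples)
  m <- dropout_zero(2^l, l, config$zero_inflation_rate)
  dimnames(m) <- list(sprintf("mir%04d", seq_len(config$n_mirna)),
                      sprintf("s%03d", seq_len(config$n_samples)))
  as_expr_tbl(m)
}

#' Simulate a protein--protein interaction network with planted modules
#'
#' Planted-partition graph: each within-module node pair is an edge with
#' probability `p_in`, each between-module pair with probability `p_out`.
#'
#' @param n_modules Number of planted modules.
#' @param module_size Nodes per module (>= 2).
#' @param p_in,p_out Within/between edge probabilities; `p_in > p_out`.
#' @param seed Integer seed.
#' @param node_ids Optional character vector of node names
#'   (length `n_modules * module_size`); defaults to `n0001`, ...
#' @return An object of class `synthetic_network`: list with an `edges`
#'   tibble (`from`, `to`) and a `truth_modules` tibble (`gene_id`,
#'   `module`).
#' @examples
#' net <- simulate_ppi(4, 20, p_in = 0.3, p_out = 0.02, seed = 7)
#' nrow(net$edges)
#' @export
simulate_ppi <- function(n_modules, module_size, p_in, p_out, seed,
                         node_ids = NULL) {
  if (module_size < 2) stop("module_size must be >= 2", call. = FALSE)
  if (n_modules < 1) stop("n_modules must be >= 1", call. = FALSE)
  if (!(p_in > p_out)) stop("p_in must exceed p_out", call. = FALSE)
  stopifnot(p_in <= 1, p_out >= 0)
  n <- n_modules * module_size
  if (is.null(node_ids)) node_ids <- sprintf("n%04d", seq_len(n))
  stopifnot(length(node_ids) == n, !anyDuplicated(node_ids))

  set.seed(as.integer(seed))
  module <- rep(seq_len(n_modules), each = module_size)
  pair <- utils::combn(n, 2)
  same <- module[pair[1, ]] == module[pair[2, ]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pair)) < p
  edges <- tibble::tibble(from = node_ids[pair[1, keep]],
                          to = node_ids[pair[2, keep]])

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = node_ids)
  ncomp <- igraph::count_components(g)
  message("simulated PPI network: ", n, " nodes, ", nrow(edges), " edges, ",
          ncomp, " connected component(s)")

  structure(list(
    edges = edges,
    truth_modules = tibble::tibble(gene_id = node_ids,
                                   module = paste0("M", module))
  ), class = "synthetic_network")
}
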